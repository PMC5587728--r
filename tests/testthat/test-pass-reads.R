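# A tiny hand-built reference and SAM exercising the CIGAR/strand rules.
mini_genome <- function() {
  # no T in the first 10 bases, so clips at position 10 are never
  # absorbed as genomic sequence
  #            0         1         2         3         4         5
  #            0123456789012345678901234567890123456789012345678901
  seqs <- c(ctg = paste0("CGCGAACGCCACGATCGGCATGCATGCCGTAGCATGCAGCAT",
                         "GCCGGCGCTAGC"))
  Biostrings::DNAStringSet(seqs)
}

mini_sam <- function(lines) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:ctg\tLN:54", lines),
             path)
  path
}

test_that("SAM parsing extracts the 5'-side soft clip per strand", {
  sam <- mini_sam(c(
    # forward, leading 4S: clip in read orientation is the raw clip
    "r1\t0\tctg\t11\t30\t4S10M\t*\t0\t0\tTTTTTACGATCGGC\t*",
    # reverse, trailing 4S: clip reverse-complemented into read orientation
    "r2\t16\tctg\t11\t30\t10M4S\t*\t0\t0\tTACGATCGGCAAAA\t*",
    # secondary alignment: skipped
    "r3\t256\tctg\t11\t30\t14M\t*\t0\t0\tTACGATCGGCATGC\t*",
    # unmapped: skipped
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"))
  rec <- read_alignments(sam)
  expect_equal(sort(rec$read_id), c("r1", "r2"))
  r1 <- rec[rec$read_id == "r1", ]
  expect_equal(r1$strand, "+")
  expect_equal(r1$clip5_len, 4L)
  expect_equal(r1$clip5_bases, "TTTT")
  expect_equal(c(r1$start0, r1$end0), c(10L, 20L))
  r2 <- rec[rec$read_id == "r2", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$clip5_len, 4L)
  expect_equal(r2$clip5_bases, "TTTT")   # revcomp of trailing AAAA
  expect_equal(c(r2$start0, r2$end0), c(10L, 20L))
  expect_error(read_alignments(tempfile()), "no such file")
})

test_that("PASS rules enforce MAPQ, clip presence and tail length", {
  g <- mini_genome()
  rec <- data.frame(
    read_id = c("low", "noclip", "short", "good"),
    contig = "ctg", start0 = 10L, end0 = 20L, strand = "+",
    mapq = c(5L, 30L, 30L, 30L),
    clip5_len = c(4L, 0L, 1L, 3L),
    clip5_bases = c("TTTT", "", "T", "TTT"),
    clip_sam = c("TTTT", "", "T", "TTT"),
    unique = TRUE, stringsAsFactors = FALSE)
  res <- identify_pass_reads(rec, g, "s1")
  expect_equal(res$rejections$reason[match(c("low", "noclip", "short"),
                                           res$rejections$read_id)],
               c("low_mapq", "no_clip", "insufficient_tail"))
  expect_equal(res$events$read_id, "good")
  expect_equal(res$events$n_tail_ts, 3L)
  # forward alignment evidences a minus-strand PAS at the first aligned base
  expect_equal(res$events$strand, "-")
  expect_equal(res$events$position, 10L)
  # MAPQ exactly 10 is still rejected (rule is MAPQ > 10), 11 passes
  rec2 <- rec[rec$read_id == "good", ]
  rec2$mapq <- 10L
  expect_equal(identify_pass_reads(rec2, g, "s1")$rejections$reason,
               "low_mapq")
  rec2$mapq <- 11L
  expect_equal(nrow(identify_pass_reads(rec2, g, "s1")$events), 1L)
  # non-unique alignments are rejected
  rec3 <- rec[rec$read_id == "good", ]
  rec3$unique <- FALSE
  expect_equal(identify_pass_reads(rec3, g, "s1")$rejections$reason,
               "not_unique")
  expect_error(identify_pass_reads(transform(rec, contig = "nope"), g, "s"),
               "contig missing")
})

test_that("clipped Ts matching the adjacent reference are subtracted", {
  # reference: ...CGTT | ACGATC...  (positions 6..9 are GTTA around start 10)
  g <- Biostrings::DNAStringSet(c(ctg = paste0(
    "CGCGTATTTTACGATCGGCATGCATGCCGTAGCATGCAGCATGCCGGCGCTAGC")))
  # forward alignment starting at 0-based 10 ("CGATC..."); wait: base 10 is
  # the 11th character "C"; upstream bases 6..9 are "TTTT" -> a clip of
  # four Ts could extend entirely, leaving no non-genomic tail
  rec <- data.frame(read_id = "r", contig = "ctg", start0 = 10L, end0 = 20L,
                    strand = "+", mapq = 30L, clip5_len = 4L,
                    clip5_bases = "TTTT", clip_sam = "TTTT", unique = TRUE,
                    stringsAsFactors = FALSE)
  res <- identify_pass_reads(rec, g, "s1")
  expect_equal(res$rejections$reason, "insufficient_tail")
  # with only two genomic Ts adjacent, two of four clip Ts survive
  g2 <- Biostrings::DNAStringSet(c(ctg = paste0(
    "CGCGTAGCTTACGATCGGCATGCATGCCGTAGCATGCAGCATGCCGGCGCTAGC")))
  res2 <- identify_pass_reads(rec, g2, "s1")
  expect_equal(res2$events$n_tail_ts, 2L)
  # cleavage position moves outward past the absorbed genomic bases
  expect_equal(res2$events$position, 10L - 2L)
  # reverse alignment mirror: trailing clip AAAA with genomic As adjacent
  g3 <- Biostrings::DNAStringSet(c(ctg = paste0(
    "CGCGTAGCTTACGATCGGCAAGCATGCCGTAGCATGCAGCATGCCGGCGCTAGC")))
  rec3 <- data.frame(read_id = "r", contig = "ctg", start0 = 10L,
                     end0 = 20L, strand = "-", mapq = 30L, clip5_len = 4L,
                     clip5_bases = "TTTT", clip_sam = "AAAA", unique = TRUE,
                     stringsAsFactors = FALSE)
  res3 <- identify_pass_reads(rec3, g3, "s1")
  # reference at 20,21 is "AG": one A absorbed, three tail Ts remain
  expect_equal(res3$events$n_tail_ts, 3L)
  expect_equal(res3$events$position, 19L + 1L)
  expect_equal(res3$events$strand, "+")
})

test_that("every record becomes exactly one event or one rejection", {
  cfg <- small_config(seed = 61L)
  fx <- simulate_fixture(cfg)
  rec <- records_from_reads(fx$reads$kd)
  res <- identify_pass_reads(rec, fx$assets$genome, "kd")
  expect_equal(nrow(res$events) + nrow(res$rejections), nrow(rec))
  expect_equal(length(intersect(res$events$read_id,
                                res$rejections$read_id)), 0L)
  # PASS set equals the truth-table prediction exactly
  truth_pass <- fx$reads$kd$mapq > 10L & fx$reads$kd$tail_k >= 2L
  expect_equal(nrow(res$events), sum(truth_pass))
  expect_setequal(res$events$read_id, fx$reads$kd$qname[truth_pass])
})

test_that("mirrored genomes give mirrored cleavage positions", {
  cfg <- sim_config(n_genes = 5L, n_reads = 800L, seed = 71L)
  fx <- simulate_fixture(cfg)
  rec <- records_from_reads(fx$reads$ctrl)
  res <- identify_pass_reads(rec, fx$assets$genome, "s")$events
  # reverse-complement the contig and flip every alignment accordingly
  L <- length(fx$assets$genome[[1L]])
  mg <- Biostrings::reverseComplement(fx$assets$genome)
  names(mg) <- names(fx$assets$genome)
  mrec <- rec
  mrec$start0 <- L - rec$end0
  mrec$end0 <- L - rec$start0
  mrec$strand <- ifelse(rec$strand == "+", "-", "+")
  mrec$clip_sam <- vapply(rec$clip_sam, function(s) {
    if (nchar(s)) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))) else s
  }, character(1), USE.NAMES = FALSE)
  mres <- identify_pass_reads(mrec, mg, "s")$events
  expect_equal(nrow(mres), nrow(res))
  m <- merge(res, mres, by = "read_id")
  expect_equal(m$position.y, L - 1L - m$position.x)
  expect_true(all(m$strand.y != m$strand.x))
})

test_that("tallying preserves totals and separates strands", {
  ev <- data.frame(
    read_id = sprintf("r%d", 1:5), contig = "c",
    position = c(10L, 10L, 10L, 10L, 12L),
    strand = c("+", "+", "+", "-", "+"),
    sample_id = c("a", "a", "a", "a", "b"),
    n_tail_ts = 2L, stringsAsFactors = FALSE)
  tal <- tally_cleavage_sites(ev)
  expect_equal(sum(tal$count), 5L)
  expect_equal(tal$count[tal$position == 10 & tal$strand == "+" &
                           tal$sample_id == "a"], 3L)
  expect_equal(nrow(tal[tal$position == 10, ]), 2L)   # strands kept apart
  expect_equal(nrow(tally_cleavage_sites(ev[0, ])), 0L)
})
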
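tally_of <- function(pos, count, strand = "+", sample = "s1",
                     contig = "c") {
  data.frame(contig = contig, strand = strand, position = as.integer(pos),
             sample_id = sample, count = as.integer(count),
             stringsAsFactors = FALSE)
}

test_that("greedy 24-nt clustering picks representatives by pooled count", {
  # single site clusters with itself
  cl <- cluster_cleavage_sites(tally_of(100, 5))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$position, 100L)
  # 100(10), 110(5), 140(3): 110 joins 100; 140 is 40 nt away
  cl <- cluster_cleavage_sites(tally_of(c(100, 110, 140), c(10, 5, 3)))
  expect_equal(sort(cl$clusters$position), c(100L, 140L))
  expect_equal(cl$sites$cluster_id[cl$sites$position == 110],
               cl$sites$cluster_id[cl$sites$position == 100])
  expect_equal(cl$clusters$count[cl$clusters$position == 100], 15L)
  # equal counts 24 nt apart: one cluster, 5'-most representative
  cl <- cluster_cleavage_sites(tally_of(c(200, 224), c(4, 4)))
  expect_equal(cl$clusters$position, 200L)
  # on the minus strand the 5'-most site is the larger coordinate
  cl <- cluster_cleavage_sites(tally_of(c(200, 224), c(4, 4), strand = "-"))
  expect_equal(cl$clusters$position, 224L)
  # members beyond the window from the representative stay apart
  cl <- cluster_cleavage_sites(tally_of(c(100, 125), c(9, 1)))
  expect_equal(nrow(cl$clusters), 2L)
})

test_that("clustering matches the brute-force oracle on random instances", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    pos <- sample(0:300, n)
    cnt <- sample(1:40, n, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    got <- cluster_cleavage_sites(tally_of(pos, cnt, strand = strand))
    want <- oracle_cluster(pos, cnt, strand = strand)
    got_rep <- got$sites$cluster_id[match(pos, got$sites$position)]
    expect_equal(as.integer(sub("^c:(\\d+):.*", "\\1", got_rep)), want)
  }
})

test_that("cluster per-sample counts conserve the assigned events", {
  tal <- rbind(tally_of(c(100, 103), c(3, 2), sample = "a"),
               tally_of(c(100, 150), c(1, 7), sample = "b"))
  cl <- cluster_cleavage_sites(tal)
  expect_equal(sum(cl$counts$count), sum(tal$count))
  cid <- cl$sites$cluster_id[cl$sites$position == 100]
  cc <- cl$counts[cl$counts$cluster_id == cid, ]
  expect_equal(cc$count[cc$sample_id == "a"], 5L)
  expect_equal(cc$count[cc$sample_id == "b"], 1L)
})

test_that("gene and region annotation honors spans, extensions and strand", {
  ann <- data.frame(
    gene_id = c("gA", "gB"), contig = "c", strand = c("+", "-"),
    gene_start = c(1000L, 20000L), gene_end = c(5000L, 24000L),
    last_exon_start = c(4000L, 20000L), last_exon_end = c(5000L, 21000L),
    biotype = c("mRNA", "lncRNA"), stringsAsFactors = FALSE)
  tal <- rbind(
    tally_of(4500, 5),             # gA last exon
    tally_of(2000, 5),             # gA intron upstream of last exon
    tally_of(8000, 5),             # 3 kb downstream of gA end, extension
    tally_of(500, 5),              # intergenic
    tally_of(20500, 5, strand = "-"),  # gB last exon (3' end at low coords)
    tally_of(23000, 5, strand = "-"),  # gB upstream region
    tally_of(4500, 5, strand = "-"))   # inside gA span but wrong strand
  cl <- annotate_pas_location(cluster_cleavage_sites(tal), ann,
                              extension = 4000L)
  x <- cl$clusters
  at <- function(pos, strand = "+")
    x[x$position == pos & x$strand == strand, ]
  expect_equal(at(4500)$gene_id, "gA")
  expect_equal(at(4500)$region, "three_prime_region")
  expect_equal(at(2000)$region, "upstream")
  expect_equal(at(8000)$gene_id, "gA")
  expect_equal(at(8000)$region, "three_prime_region")
  expect_true(is.na(at(500)$gene_id))
  expect_equal(at(20500, "-")$gene_id, "gB")
  expect_equal(at(20500, "-")$region, "three_prime_region")
  expect_equal(at(23000, "-")$region, "upstream")
  expect_true(is.na(at(4500, "-")$gene_id))
  expect_equal(at(20500, "-")$biotype, "lncRNA")
})

test_that("support filtering requires both conditions in the same sample", {
  ann <- data.frame(gene_id = "g", contig = "c", strand = "+",
                    gene_start = 0L, gene_end = 1000L,
                    last_exon_start = 500L, last_exon_end = 1000L,
                    biotype = "mRNA", stringsAsFactors = FALSE)
  build <- function(counts_a, counts_b) {
    # three PASs far apart; per-sample counts as given
    tal <- rbind(tally_of(c(600, 700, 800), counts_a, sample = "a"),
                 tally_of(c(600, 700, 800), counts_b, sample = "b"))
    tal <- tal[tal$count > 0, ]
    annotate_pas_location(cluster_cleavage_sites(tal), ann)
  }
  # one read in each sample: never retained
  cl <- build(c(1, 100, 0), c(1, 0, 100))
  f <- filter_pas_clusters(cl)
  expect_false(600 %in% f$clusters$position)
  # 10 reads but only 4% of the gene in its sample: not retained
  cl <- build(c(10, 240, 0), c(0, 0, 100))
  f <- filter_pas_clusters(cl)
  expect_false(600 %in% f$clusters$position)
  # conditions met jointly in one sample: retained
  cl <- build(c(3, 47, 0), c(0, 0, 100))
  f <- filter_pas_clusters(cl)
  expect_true(600 %in% f$clusters$position)
  # support split so neither sample satisfies both conditions
  cl <- build(c(1, 10, 0), c(40, 1000, 0))
  f <- filter_pas_clusters(cl)
  expect_false(600 %in% f$clusters$position)
  expect_error(filter_pas_clusters(cluster_cleavage_sites(
    tally_of(1, 5))), "annotated")
})

test_that("relaxing filter thresholds never shrinks the retained set", {
  cfg <- small_config(seed = 91L)
  fx <- simulate_fixture(cfg)
  cl <- atlas_from_fixture(fx, min_reads = 0L, min_frac = 0)
  base <- atlas_from_fixture(fx)
  for (mr in c(1L, 2L, 5L)) {
    for (mf in c(0.01, 0.05, 0.2)) {
      strict <- atlas_from_fixture(fx, min_reads = mr, min_frac = mf)
      loose <- atlas_from_fixture(fx, min_reads = mr - 1L,
                                  min_frac = mf / 2)
      expect_true(all(strict$clusters$cluster_id %in%
                        loose$clusters$cluster_id))
    }
  }
  expect_true(all(base$clusters$cluster_id %in% cl$clusters$cluster_id))
})

test_that("poly(A)-signal classes follow the hierarchy", {
  pad <- function(x) paste0(strrep("G", 40 - nchar(x) - 2), x, "GC")
  expect_equal(as.character(classify_pas_signal(pad("AATAAA"))), "AAUAAA")
  expect_equal(as.character(classify_pas_signal(pad("ATTAAA"))), "variant")
  expect_equal(as.character(classify_pas_signal(pad("AUUAAA"))), "variant")
  # canonical beats variant when both present
  expect_equal(as.character(classify_pas_signal(
    paste0("ATTAAA", strrep("C", 20), "AATAAA", strrep("G", 8)))),
    "AAUAAA")
  expect_equal(as.character(classify_pas_signal(pad("AAAGAA"))), "A_rich")
  expect_equal(as.character(classify_pas_signal(
    paste(rep(c("G", "C"), 20), collapse = ""))), "none")
  expect_equal(as.character(classify_pas_signal("GC")), "none")
  expect_error(classify_pas_signal("ACGTNACGT"), "alphabet")
  # all ten default variants classify as variant
  for (v in apatlas:::PAS_SIGNAL_VARIANTS) {
    expect_equal(as.character(classify_pas_signal(pad(v))), "variant")
  }
})

test_that("atlas BED export is well-formed", {
  tal <- tally_of(c(100, 200), c(5, 7))
  cl <- cluster_cleavage_sites(tal)
  path <- tempfile(fileext = ".bed")
  write_pas_bed(cl, path)
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(ncol(bed), 6L)
  expect_equal(bed$V2 + 1L, bed$V3)
  expect_equal(sort(bed$V5), c(5L, 7L))
  expect_true(all(bed$V6 == "+"))
})
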
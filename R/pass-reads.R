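#' PASS read identification
#'
#' A PAS-supporting (PASS) read is a uniquely mapped read (MAPQ > 10)
#' carrying at least two additional 5' Ts that cannot be aligned to the
#' genome — residue of the poly(A) tail left on the read after cleavage.
#' Because the reads are reverse complements of transcript 3' ends, the
#' tail appears in SAM orientation as a trailing soft-clipped A-stretch on
#' reverse-strand alignments and a leading soft-clipped T-stretch on
#' forward alignments. Soft-clipped tail bases that exactly match the
#' reference when the alignment is extended outward are treated as
#' genomic (they could have been aligned, and may reflect internal
#' priming) and are subtracted from the tail count.
#'
#' @name pass_reads
NULL

#' Read aligned records from a SAM file
#'
#' Parses a SAM file, skips unmapped, secondary and supplementary
#' records, and extracts the 5'-side soft clip of every read in read
#' orientation: the leading soft clip for forward alignments, and the
#' reverse complement of the trailing soft clip for reverse alignments.
#'
#' @param sam_path path to a SAM (or BAM) file with an `@SQ` header.
#' @return a data.frame with one row per primary mapped record:
#'   `read_id`, `contig`, `start0`/`end0` (0-based half-open reference
#'   span), `strand` (alignment strand), `mapq`, `clip5_len`,
#'   `clip5_bases` (read orientation), `clip_sam` (SAM orientation, for
#'   reference comparison) and `unique` (primary-alignment flag).
#' @export
read_alignments <- function(sam_path) {
  if (!file.exists(sam_path)) stop("no such file: ", sam_path)
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(0), contig = character(0),
                      start0 = integer(0), end0 = integer(0),
                      strand = character(0), mapq = integer(0),
                      clip5_len = integer(0), clip5_bases = character(0),
                      clip_sam = character(0), unique = logical(0),
                      stringsAsFactors = FALSE))
  }
  reverse <- bitwAnd(x$flag, 16L) > 0L
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  ops <- GenomicAlignments::explodeCigarOps(x$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(x$cigar)
  lead_s <- mapply(function(o, l) if (length(o) && o[1L] == "S") l[1L] else 0L,
                   ops, lens)
  trail_s <- mapply(function(o, l) {
    m <- length(o)
    if (m && o[m] == "S") l[m] else 0L
  }, ops, lens)
  seqs <- as.character(x$seq)
  seqw <- nchar(seqs)
  clip_sam_len <- ifelse(reverse, trail_s, lead_s)
  clip_sam <- ifelse(reverse,
                     substring(seqs, seqw - trail_s + 1L, seqw),
                     substring(seqs, 1L, lead_s))
  clip5 <- clip_sam
  has_rev_clip <- reverse & clip_sam_len > 0L
  if (any(has_rev_clip)) clip5[has_rev_clip] <- revcomp(clip_sam[has_rev_clip])

  data.frame(read_id = x$qname, contig = as.character(x$rname),
             start0 = x$pos - 1L, end0 = x$pos - 1L + refw,
             strand = ifelse(reverse, "-", "+"), mapq = x$mapq,
             clip5_len = clip_sam_len, clip5_bases = clip5,
             clip_sam = clip_sam, unique = TRUE,
             stringsAsFactors = FALSE)
}

# Vectorized common-prefix length of two equal-length character vectors.
common_prefix_len <- function(a, b) {
  n <- length(a)
  out <- integer(n)
  alive <- nchar(a) > 0L & nchar(b) > 0L
  j <- 1L
  while (any(alive)) {
    same <- alive & substr(a, j, j) == substr(b, j, j) &
      nchar(a) >= j & nchar(b) >= j
    out[same] <- j
    alive <- same & nchar(a) > j & nchar(b) > j
    j <- j + 1L
  }
  out
}

#' Identify PASS reads and their cleavage events
#'
#' Applies the PASS rules to aligned records: rejects non-unique or
#' low-MAPQ alignments (MAPQ must exceed 10), requires a 5'-side soft
#' clip, subtracts clipped bases that match the reference when extending
#' the alignment outward, and accepts reads whose remaining contiguous 5'
#' T-stretch is at least `min_tail` long. The cleavage position is the
#' last transcribed nucleotide — the aligned base abutting the clip
#' (after genomic-match absorption) — and the PAS strand is the opposite
#' of the alignment strand.
#'
#' @param records data.frame from [read_alignments].
#' @param genome named `DNAStringSet` reference.
#' @param sample_id label attached to emitted events.
#' @param min_tail minimum number of non-genomic tail Ts (default 2).
#' @param max_mapq_rejected alignments with MAPQ at or below this value
#'   are rejected (default 10).
#' @return list with `events` (one row per PASS read: `contig`,
#'   `position` 0-based, `strand` of the PAS, `sample_id`, `n_tail_ts`)
#'   and `rejections` (`read_id`, `reason` in `low_mapq`, `not_unique`,
#'   `no_clip`, `insufficient_tail`). Every input record lands in exactly
#'   one of the two.
#' @export
identify_pass_reads <- function(records, genome, sample_id,
                                min_tail = 2L, max_mapq_rejected = 10L) {
  n <- nrow(records)
  missing_ctg <- setdiff(unique(records$contig), names(genome))
  if (length(missing_ctg)) {
    stop("reference contig missing from genome: ",
         paste(missing_ctg, collapse = ", "))
  }
  reason <- rep(NA_character_, n)
  reason[records$mapq <= max_mapq_rejected] <- "low_mapq"
  reason[is.na(reason) & !records$unique] <- "not_unique"
  reason[is.na(reason) & records$clip5_len == 0L] <- "no_clip"

  cand <- which(is.na(reason))
  absorbed <- integer(n)
  tail_ts <- integer(n)
  if (length(cand)) {
    contig_seqs <- vapply(names(genome), function(nm)
      as.character(genome[[nm]]), character(1))
    cs <- contig_seqs[records$contig[cand]]
    fwd <- records$strand[cand] == "+"
    len <- records$clip5_len[cand]
    # reference window adjacent to the clip, in outward direction
    ref_out <- character(length(cand))
    clip_out <- character(length(cand))
    # forward alignment: clip precedes start0; outward = leftward, so
    # compare the reversed clip to the reversed upstream reference
    if (any(fwd)) {
      i <- which(fwd)
      s0 <- records$start0[cand][i]
      win <- substring(cs[i], pmax(s0 - len[i], 0L) + 1L, s0)
      revstr <- function(z) as.character(
        Biostrings::reverse(Biostrings::BStringSet(z)))
      ref_out[i] <- revstr(win)
      clip_out[i] <- revstr(records$clip_sam[cand][i])
    }
    # reverse alignment: trailing clip follows end0; outward = rightward
    if (any(!fwd)) {
      i <- which(!fwd)
      e0 <- records$end0[cand][i]
      ref_out[i] <- substring(cs[i], e0 + 1L, e0 + len[i])
      clip_out[i] <- records$clip_sam[cand][i]
    }
    a <- common_prefix_len(clip_out, ref_out)
    absorbed[cand] <- a
    # contiguous T-stretch from the read 5' end of the remaining clip
    t_run <- attr(regexpr("^T*", records$clip5_bases[cand]), "match.length")
    tail_ts[cand] <- pmin(t_run, len - a)
    reason[cand[tail_ts[cand] < min_tail]] <- "insufficient_tail"
  }

  keep <- which(is.na(reason))
  fwd_k <- records$strand[keep] == "+"
  events <- data.frame(
    read_id = records$read_id[keep],
    contig = records$contig[keep],
    position = ifelse(fwd_k, records$start0[keep] - absorbed[keep],
                      records$end0[keep] - 1L + absorbed[keep]),
    strand = ifelse(fwd_k, "-", "+"),
    sample_id = if (length(keep)) sample_id else character(0),
    n_tail_ts = tail_ts[keep],
    stringsAsFactors = FALSE)
  rej <- which(!is.na(reason))
  rejections <- data.frame(read_id = records$read_id[rej],
                           reason = reason[rej], stringsAsFactors = FALSE)
  list(events = events, rejections = rejections)
}

#' Tally cleavage events into per-site counts
#'
#' @param events data.frame of cleavage events (from
#'   [identify_pass_reads], possibly concatenated across samples).
#' @return data.frame of exact integer counts per
#'   (`contig`, `strand`, `position`, `sample_id`).
#' @export
tally_cleavage_sites <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      position = integer(0), sample_id = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(
    events[, c("contig", "strand", "position", "sample_id")])
  out <- dt[, list(count = .N), by = c("contig", "strand", "position",
                                       "sample_id")]
  out <- as.data.frame(out)
  out[order(out$contig, out$strand, out$position, out$sample_id), ,
      drop = FALSE]
}
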
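#' Motif analyses around PASs
#'
#' Sequence analyses of the -100..+100 region around cleavage sites:
#' PFM-based binding-score meta-profiles (LOWESS-smoothed), mean upstream
#' scores in the -100..-41 region, score-percentile group comparisons of
#' expression changes (K-S test), k-mer enrichment between PAS groups
#' (Fisher exact on per-sequence presence) and poly(A)-signal composition
#' tests (chi-square).
#'
#' @name motif_analysis
NULL

#' Average PFM score profile across a PAS set
#'
#' Scans each flank with the PFM, averages scores position-wise across
#' the set, and smooths the mean curve with LOWESS (default smoother
#' span 0.05). Robustness iterations are off by default: they would
#' treat a genuine sharp peak — a motif planted at a fixed offset — as
#' an outlier and flatten it. Flanks shorter than the longest length
#' (contig-edge truncations) are dropped with a warning.
#'
#' @param flanks character vector of -100..+100 flanks in transcript
#'   orientation (see [pas_flank]).
#' @param pfm a [pfm] object.
#' @param upstream nucleotides of flank 5' of the cleavage site
#'   (default 100).
#' @param span LOWESS smoother span (default 0.05).
#' @param iter LOWESS robustness iterations (default 0).
#' @return data.frame of class `motif_profile` with `position` (k-mer
#'   start relative to the cleavage site), `score` (mean raw) and
#'   `smoothed`.
#' @export
build_meta_profile <- function(flanks, pfm, upstream = 100L, span = 0.05,
                               iter = 0L) {
  stopifnot(length(flanks) >= 1L)
  len <- nchar(flanks)
  full <- max(len)
  if (any(len < full)) {
    warning(sum(len < full), " truncated flank(s) dropped from the profile")
    flanks <- flanks[len == full]
  }
  scans <- vapply(flanks, scan_pas_region, pfm = pfm, upstream = upstream,
                  FUN.VALUE = numeric(full - nrow(pfm) + 1L),
                  USE.NAMES = FALSE)
  score <- rowMeans(scans)
  position <- seq_len(length(score)) - upstream - 1L
  smoothed <- stats::lowess(position, score, f = span, iter = iter)$y
  structure(data.frame(position = position, score = score,
                       smoothed = smoothed),
            class = c("motif_profile", "data.frame"))
}

#' Mean PFM score in an upstream window
#'
#' Averages the scores of all k-mers lying entirely within the given
#' region relative to the cleavage site (default -100..-41, i.e. start
#' positions -100..-47 for a 7-wide PFM). With `partial = TRUE`, k-mers
#' merely overlapping the region are included as well.
#'
#' @param flanks character vector of flanks in transcript orientation.
#' @param pfm a [pfm] object.
#' @param region length-2 integer vector, inclusive bounds relative to
#'   the cleavage site (position 0 = last transcribed nucleotide).
#' @param upstream flank extent 5' of the cleavage site (default 100).
#' @param partial include k-mers partially overlapping the region edge.
#' @return numeric vector of per-flank mean scores (NA when a truncated
#'   flank contains no eligible window).
#' @export
mean_upstream_score <- function(flanks, pfm, region = c(-100L, -41L),
                                upstream = 100L, partial = FALSE) {
  w <- nrow(pfm)
  if (region[2L] - region[1L] + 1L < w) {
    stop("region shorter than the PFM width")
  }
  starts <- if (partial) (region[1L] - w + 1L):region[2L] else
    region[1L]:(region[2L] - w + 1L)
  vapply(flanks, function(fl) {
    sc <- scan_pas_region(fl, pfm, upstream = upstream)
    sel <- names(sc) %in% as.character(starts)
    if (!any(sel)) return(NA_real_)
    mean(sc[sel])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compare expression changes between motif-score percentile groups
#'
#' Splits units into groups by motif-score percentile and compares the
#' paired values (log2 fold changes or delta RED) between the designated
#' groups with a two-sided two-sample K-S test. With `cut = "90th"` the
#' high group is scores strictly above the 90th percentile and the low
#' group everything else; with `cut = "10th/90th"` the tails are
#' compared (scores at the cutoffs go to the lower-score group).
#' Percentiles use linear interpolation.
#'
#' @param scores numeric vector of per-unit motif scores.
#' @param values numeric vector of per-unit expression changes.
#' @param cut `"90th"` or `"10th/90th"`.
#' @return list with `group` (factor `low`/`mid`/`high` per unit),
#'   `cutoffs`, `statistic` and `p_value` (NA with a warning when a
#'   group is empty or the score distribution is degenerate).
#' @export
percentile_group_ks <- function(scores, values, cut = c("90th",
                                                        "10th/90th")) {
  cut <- match.arg(cut)
  stopifnot(length(scores) == length(values))
  if (length(scores) < 20L) stop("need at least 20 units")
  if (cut == "90th") {
    q <- stats::quantile(scores, 0.9, type = 7)
    grp <- factor(ifelse(scores > q, "high", "low"),
                  levels = c("low", "high"))
    cutoffs <- c(`90%` = unname(q))
  } else {
    q <- stats::quantile(scores, c(0.1, 0.9), type = 7)
    grp <- factor(ifelse(scores > q[2L], "high",
                         ifelse(scores <= q[1L], "low", "mid")),
                  levels = c("low", "mid", "high"))
    cutoffs <- q
  }
  a <- values[grp == "low"]
  b <- values[grp == "high"]
  if (length(a) == 0L || length(b) == 0L) {
    warning("degenerate score grouping; K-S p-value undefined")
    return(list(group = grp, cutoffs = cutoffs, statistic = NA_real_,
                p_value = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(b, a, alternative = "two.sided"))
  list(group = grp, cutoffs = cutoffs,
       statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Extract a fixed region from PAS flanks
#'
#' @param flanks character vector of flanks in transcript orientation.
#' @param region length-2 inclusive bounds relative to the cleavage site
#'   (one of -100..-41, -40..-1, +1..+40, +41..+100 in the standard
#'   analysis).
#' @param upstream flank extent 5' of the cleavage site (default 100).
#' @return character vector of region subsequences.
#' @export
flank_region <- function(flanks, region, upstream = 100L) {
  substr(flanks, region[1L] + upstream + 1L, region[2L] + upstream + 1L)
}

#' k-mer enrichment between PAS groups
#'
#' For each of the 4^k k-mers, counts the sequences containing it in the
#' group and background sets and tests the 2x2 presence/absence table
#' with the two-sided Fisher exact test.
#'
#' @param group_seqs,background_seqs character vectors of region
#'   sequences (see [flank_region]).
#' @param k k-mer length (default 4).
#' @return data.frame with one row per k-mer (RNA alphabet): presence
#'   counts, set sizes, `p_value` and `neg_log10_p`, sorted by p-value.
#' @export
kmer_enrichment <- function(group_seqs, background_seqs, k = 4L) {
  if (length(group_seqs) == 0L || length(background_seqs) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  kmers <- do.call(paste0, rev(expand.grid(
    rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE)))
  pd <- Biostrings::DNAStringSet(kmers)
  count_with <- function(seqs) {
    m <- Biostrings::vcountPDict(pd,
                                 Biostrings::DNAStringSet(as_dna(seqs)))
    as.integer(rowSums(m > 0))
  }
  gw <- count_with(group_seqs)
  bw <- count_with(background_seqs)
  gn <- length(group_seqs)
  bn <- length(background_seqs)
  p <- fisher_p_2x2(gw, gn - gw, bw, bn - bw)
  out <- data.frame(kmer = chartr("T", "U", kmers),
                    group_with = gw, group_n = gn,
                    background_with = bw, background_n = bn,
                    p_value = p, neg_log10_p = -log10(p),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$kmer), ]
}

#' Poly(A)-signal composition test between PAS groups
#'
#' Tabulates signal classes per group, reports class proportions, and
#' tests homogeneity between a designated pair of groups with the
#' chi-square test; when any expected cell drops below 1 it falls back
#' to the Fisher exact test with a warning.
#'
#' @param signal_class factor from [classify_pas_signal].
#' @param group factor of PAS group labels, same length.
#' @param pair length-2 character vector of groups to test.
#' @return list with `table` (group x class counts), `proportions`
#'   (rows sum to 1), `method`, `statistic` and `p_value`.
#' @export
signal_composition_test <- function(signal_class, group, pair) {
  stopifnot(length(signal_class) == length(group), length(pair) == 2L)
  tab <- table(group = group, class = signal_class)
  props <- prop.table(tab, margin = 1L)
  sub <- tab[pair, colSums(tab[pair, , drop = FALSE]) > 0, drop = FALSE]
  expected <- outer(rowSums(sub), colSums(sub)) / sum(sub)
  if (any(expected < 1)) {
    warning("expected cell count below 1; using Fisher's exact test")
    ft <- stats::fisher.test(sub, workspace = 2e7)
    return(list(table = tab, proportions = props, method = "fisher",
                statistic = NA_real_, p_value = ft$p.value))
  }
  ct <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
  list(table = tab, proportions = props, method = "chisq",
       statistic = unname(ct$statistic), p_value = ct$p.value)
}
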
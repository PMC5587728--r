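#' APA significance and trend statistics
#'
#' For each gene with two comparable PAS isoforms (or PAS groups), the
#' isoform-by-sample 2x2 read-count table is tested for an isoform switch
#' with a two-sided exact conditional test (Fisher), adjusted with
#' Benjamini-Hochberg FDR. The relative expression difference (RED) is
#' the log2 ratio of distal to proximal isoform reads; delta RED compares
#' RED between knockdown and control, so negative delta RED means 3'UTR
#' shortening. A global trend is summarized as the log2 ratio of the
#' number of genes changing in each direction.
#'
#' @name apa_stats
NULL

# Vectorized two-sided Fisher exact p for 2x2 tables [[a, b], [c, d]]
# (conditioning on margins; p sums hypergeometric point probabilities not
# exceeding the observed one, with the customary 1e-7 relative slack).
fisher_p_2x2 <- function(a, b, c, d) {
  if (length(a) == 0L) return(numeric(0))
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- pmax(0L, k - m2)
  hi <- pmin(k, m1)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- numeric(length(a))
  thr <- p_obs * (1 + 1e-7)
  for (y in 0L:max(hi)) {
    in_support <- y >= lo & y <= hi
    if (!any(in_support)) next
    py <- numeric(length(a))
    py[in_support] <- stats::dhyper(y, m1[in_support], m2[in_support],
                                    k[in_support])
    add <- in_support & py <= thr
    p[add] <- p[add] + py[add]
  }
  pmin(p, 1)
}

#' Exact pairwise APA test (SAAP-style) on a 2x2 count table
#'
#' Tests whether the relative expression of two PAS isoforms differs
#' between two samples, via the two-sided Fisher exact test on the
#' isoform x sample read-count table. Tables with a zero row or column
#' margin carry no information about relative usage and are flagged
#' not-testable (p = NA).
#'
#' @param counts 2x2 numeric matrix: rows = (proximal, distal) isoforms,
#'   columns = (control, knockdown) samples.
#' @return list with `p_value` and `testable`.
#' @examples
#' saap_pair_test(matrix(c(50, 50, 50, 50), 2))$p_value  # 1
#' @export
saap_pair_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) return(list(p_value = NA_real_, testable = FALSE))
  list(p_value = fisher_p_2x2(counts[1L, 1L], counts[1L, 2L],
                              counts[2L, 1L], counts[2L, 2L]),
       testable = TRUE)
}

#' Relative expression difference (RED)
#'
#' RED = log2((distal + pc) / (proximal + pc)); the pseudocount (default
#' 1) guards zero counts. Delta RED is `red_kd - red_ctrl`.
#'
#' @param proximal,distal read counts (vectorized).
#' @param pseudocount added to both counts.
#' @return numeric vector of RED values.
#' @export
compute_red <- function(proximal, distal, pseudocount = 1) {
  stopifnot(all(proximal >= 0), all(distal >= 0))
  log2((distal + pseudocount) / (proximal + pseudocount))
}

#' Select the 3'UTR isoform pair of each gene
#'
#' Among a gene's retained `three_prime_region` clusters, the two with
#' the highest pooled counts form the tested pair; the 5'-most of the
#' two (transcript orientation) is the proximal isoform. Genes with
#' fewer than two eligible clusters are skipped.
#'
#' @param se a `SummarizedExperiment` from [pas_count_table].
#' @return data.frame with `gene_id`, `proximal_id`, `distal_id`.
#' @export
select_utr_isoform_pair <- function(se) {
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  counts <- SummarizedExperiment::assay(se, "counts")
  rd$pooled <- rowSums(counts)
  rd <- rd[!is.na(rd$gene_id) & rd$region == "three_prime_region", ,
           drop = FALSE]
  out <- lapply(split(rd, rd$gene_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    top <- g[order(-g$pooled, g$position), ][1:2, ]
    # transcript orientation: 5'-most is the smaller coordinate on "+"
    ord <- if (top$strand[1L] == "+") order(top$position) else
      order(-top$position)
    data.frame(gene_id = top$gene_id[1L],
               proximal_id = top$cluster_id[ord[1L]],
               distal_id = top$cluster_id[ord[2L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      proximal_id = character(0),
                                      distal_id = character(0))
  rownames(out) <- NULL
  out
}

# Seeded binomial downsampling of the deeper sample's counts to the
# shallower sample's PASS depth ("taking the variation of sequencing
# depth into account").
equalize_depth <- function(tab, total_ctrl, total_kd, seed) {
  if (total_ctrl == total_kd) return(tab)
  set.seed(seed)
  if (total_kd > total_ctrl) {
    r <- total_ctrl / total_kd
    tab$proximal_kd <- stats::rbinom(nrow(tab), tab$proximal_kd, r)
    tab$distal_kd <- stats::rbinom(nrow(tab), tab$distal_kd, r)
  } else {
    r <- total_kd / total_ctrl
    tab$proximal_ctrl <- stats::rbinom(nrow(tab), tab$proximal_ctrl, r)
    tab$distal_ctrl <- stats::rbinom(nrow(tab), tab$distal_ctrl, r)
  }
  tab
}

# Shared machinery: exact test + BH FDR + RED/delta-RED + direction call
# on a table of per-gene pair counts.
apa_table_test <- function(tab, fdr_threshold, pseudocount, labels,
                           min_delta_red = 0) {
  tab$p_value <- NA_real_
  tab$testable <- !(tab$proximal_ctrl + tab$distal_ctrl == 0 |
                      tab$proximal_kd + tab$distal_kd == 0 |
                      tab$proximal_ctrl + tab$proximal_kd == 0 |
                      tab$distal_ctrl + tab$distal_kd == 0)
  t <- tab$testable
  tab$p_value[t] <- fisher_p_2x2(tab$proximal_ctrl[t], tab$proximal_kd[t],
                                 tab$distal_ctrl[t], tab$distal_kd[t])
  tab$fdr <- NA_real_
  tab$fdr[t] <- stats::p.adjust(tab$p_value[t], method = "BH")
  tab$red_ctrl <- compute_red(tab$proximal_ctrl, tab$distal_ctrl,
                              pseudocount)
  tab$red_kd <- compute_red(tab$proximal_kd, tab$distal_kd, pseudocount)
  tab$delta_red <- tab$red_kd - tab$red_ctrl
  sig <- t & !is.na(tab$fdr) & tab$fdr < fdr_threshold &
    abs(tab$delta_red) > min_delta_red
  tab$direction <- factor(
    ifelse(sig & tab$delta_red < 0, labels[1L],
           ifelse(sig & tab$delta_red > 0, labels[2L], "none")),
    levels = c(labels, "none"))
  tab
}

#' Test 3'UTR APA between two samples, gene by gene
#'
#' Builds the proximal/distal isoform pair of every eligible gene (see
#' [select_utr_isoform_pair]), optionally equalizes sequencing depth by
#' seeded binomial downsampling of the deeper sample, applies the exact
#' pairwise test with BH FDR, and calls each significant gene shortened
#' (delta RED < 0) or lengthened (delta RED > 0).
#'
#' @param se a `SummarizedExperiment` from [pas_count_table].
#' @param ctrl,kd sample (column) names.
#' @param fdr_threshold BH FDR threshold for direction calls
#'   (default 0.05).
#' @param pseudocount pseudocount for RED (default 1).
#' @param equalize logical; equalize PASS depth before testing
#'   (default TRUE).
#' @param seed seed for the downsampling draw.
#' @param min_delta_red optional minimum |delta RED| effect-size gate for
#'   direction calls (default 0 = off).
#' @return data.frame (one row per tested gene) with the pair ids, the
#'   (possibly depth-equalized) 2x2 counts, `p_value`, `testable`, `fdr`,
#'   `red_ctrl`, `red_kd`, `delta_red` and `direction`
#'   (shortened/lengthened/none).
#' @export
test_utr_apa <- function(se, ctrl, kd, fdr_threshold = 0.05,
                         pseudocount = 1, equalize = TRUE, seed = 1L,
                         min_delta_red = 0) {
  pairs <- select_utr_isoform_pair(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  tab <- data.frame(pairs,
                    proximal_ctrl = counts[pairs$proximal_id, ctrl],
                    distal_ctrl = counts[pairs$distal_id, ctrl],
                    proximal_kd = counts[pairs$proximal_id, kd],
                    distal_kd = counts[pairs$distal_id, kd],
                    row.names = NULL)
  if (equalize && nrow(tab)) {
    totals <- colSums(counts)
    tab <- equalize_depth(tab, totals[ctrl], totals[kd], seed)
  }
  apa_table_test(tab, fdr_threshold, pseudocount,
                 labels = c("shortened", "lengthened"),
                 min_delta_red = min_delta_red)
}

#' Global APA trend ratio (GAAP-style)
#'
#' log2 of the (pseudocounted) ratio of gene counts in the two change
#' directions: `log2((n_numerator + 0.5) / (n_denominator + 0.5))`. For
#' 3'UTR APA the numerator is shortened and the denominator lengthened,
#' so positive values mean net shortening. When no gene is significant
#' the trend is flagged undefined.
#'
#' @param results data.frame from [test_utr_apa] or [test_ur_apa].
#' @param numerator,denominator direction labels to count.
#' @return list with `n_numerator`, `n_denominator`, `trend` and
#'   `defined`.
#' @export
gaap_trend <- function(results, numerator = "shortened",
                       denominator = "lengthened") {
  n_num <- sum(results$direction == numerator, na.rm = TRUE)
  n_den <- sum(results$direction == denominator, na.rm = TRUE)
  list(n_numerator = n_num, n_denominator = n_den,
       trend = log2((n_num + 0.5) / (n_den + 0.5)),
       defined = (n_num + n_den) > 0L)
}

#' Test upstream-region PAS usage between two samples
#'
#' For every gene with at least one upstream-region and one 3'-region
#' cluster, reads are aggregated within the two groups per sample and
#' the same exact-test machinery is applied, with the upstream group in
#' the distal slot of the ratio: delta > 0 (relative upstream usage up
#' in the knockdown) is called `activated`, delta < 0 `suppressed`.
#'
#' @inheritParams test_utr_apa
#' @return data.frame as in [test_utr_apa] with `ur_*`/`tp_*` count
#'   columns and direction activated/suppressed/none.
#' @export
test_ur_apa <- function(se, ctrl, kd, fdr_threshold = 0.05,
                        pseudocount = 1, equalize = TRUE, seed = 1L,
                        min_delta_red = 0) {
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  counts <- SummarizedExperiment::assay(se, "counts")
  keep <- !is.na(rd$gene_id)
  dt <- data.table::data.table(gene_id = rd$gene_id[keep],
                               ur = rd$region[keep] == "upstream",
                               ctrl = counts[keep, ctrl],
                               kd = counts[keep, kd])
  agg <- dt[, list(ur_ctrl = sum(ctrl[ur]), tp_ctrl = sum(ctrl[!ur]),
                   ur_kd = sum(kd[ur]), tp_kd = sum(kd[!ur]),
                   has_both = any(ur) && any(!ur)), by = "gene_id"]
  agg <- as.data.frame(agg[agg$has_both, , drop = FALSE])
  tab <- data.frame(gene_id = agg$gene_id,
                    proximal_ctrl = agg$tp_ctrl, distal_ctrl = agg$ur_ctrl,
                    proximal_kd = agg$tp_kd, distal_kd = agg$ur_kd,
                    stringsAsFactors = FALSE)
  if (equalize && nrow(tab)) {
    totals <- colSums(counts)
    tab <- equalize_depth(tab, totals[ctrl], totals[kd], seed)
  }
  res <- apa_table_test(tab, fdr_threshold, pseudocount,
                        labels = c("suppressed", "activated"),
                        min_delta_red = min_delta_red)
  # delta > 0 means relative upstream usage up in kd: activated
  names(res)[names(res) %in% c("proximal_ctrl", "distal_ctrl",
                               "proximal_kd", "distal_kd")] <-
    c("tp_ctrl", "ur_ctrl", "tp_kd", "ur_kd")
  res
}
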
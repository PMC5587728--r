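#' PAS and gene expression quantification
#'
#' PAS isoform expression is measured in RPM: reads per million uniquely
#' mapped PASS reads in a sample. Gene expression is the sum of the RPM
#' values of the gene's retained PAS isoforms. Expression change between
#' two samples is the log2 ratio of RPM values, and a transcript is
#' called regulated when its fold change exceeds 2 (|log2fc| > 1) with
#' more than 50 supporting reads across the two samples.
#'
#' @name quantify
NULL

#' Build a PAS-by-sample count table
#'
#' @param clusters an annotated (and usually filtered) `pas_clusters`
#'   object.
#' @param conditions optional named character vector mapping sample ids
#'   to condition labels (stored in `colData`).
#' @param samples optional character vector fixing the column order;
#'   defaults to the sorted sample ids present.
#' @return a `SummarizedExperiment` with assay `counts` and row metadata
#'   (`cluster_id`, `contig`, `strand`, `position`, `gene_id`, `region`,
#'   `biotype`, and `signal_class` when present).
#' @export
pas_count_table <- function(clusters, conditions = NULL, samples = NULL) {
  cl <- clusters$clusters
  cts <- clusters$counts[clusters$counts$cluster_id %in% cl$cluster_id, ,
                         drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(cts$sample_id))
  mat <- matrix(0L, nrow = nrow(cl), ncol = length(samples),
                dimnames = list(cl$cluster_id, samples))
  mat[cbind(match(cts$cluster_id, cl$cluster_id),
            match(cts$sample_id, samples))] <- cts$count
  cd <- S4Vectors::DataFrame(sample_id = samples, row.names = samples)
  if (!is.null(conditions)) cd$condition <- unname(conditions[samples])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    rowData = S4Vectors::DataFrame(cl, row.names = cl$cluster_id),
    colData = cd)
}

#' Compute RPM values
#'
#' RPM = count / total PASS reads in the sample x 1e6, so each sample's
#' RPM column sums to exactly one million over all rows.
#'
#' @param se a `SummarizedExperiment` from [pas_count_table].
#' @return `se` with an added `rpm` assay.
#' @export
compute_rpm <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total PASS reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  SummarizedExperiment::assays(se)$rpm <-
    sweep(counts, 2L, totals, "/") * 1e6
  se
}

#' Gene-level expression
#'
#' Gene RPM (or counts) is the sum over the gene's retained PAS clusters;
#' clusters without a gene assignment are excluded.
#'
#' @param se a `SummarizedExperiment` (RPM computed for `assay = "rpm"`).
#' @param assay assay to aggregate, `"rpm"` (default) or `"counts"`.
#' @return numeric matrix, genes x samples.
#' @export
gene_level_expression <- function(se, assay = "rpm") {
  m <- SummarizedExperiment::assay(se, assay)
  gid <- SummarizedExperiment::rowData(se)$gene_id
  keep <- !is.na(gid)
  rowsum(m[keep, , drop = FALSE], gid[keep])
}

# Resolve the pseudocount (RPM units) used in log2 ratios. NULL means
# "one read" converted to the RPM scale of the mean sample depth — a
# single value applied to both samples so that zero-count units get a
# log2 ratio of exactly 0 and label swaps only flip the sign.
resolve_pseudocount <- function(pseudocount, totals) {
  if (is.null(pseudocount)) pseudocount <- 1e6 / mean(totals)
  rep(pseudocount, length(totals))
}

#' Per-unit log2 fold change between two samples
#'
#' log2((rpm_kd + pc) / (rpm_ctrl + pc)). The default pseudocount is one
#' read converted to RPM at the mean depth of the two samples, applied
#' to both sides, which stabilizes zero-count units (both-zero units get
#' log2fc exactly 0); pass a numeric value (possibly 0) to override.
#'
#' @param se a `SummarizedExperiment` with `counts` (RPM is derived
#'   internally).
#' @param kd,ctrl sample (column) names to compare.
#' @param level `"pas"` for per-cluster transcripts or `"gene"` for
#'   gene-level sums.
#' @param pseudocount `NULL` (default, 1-count RPM equivalent) or a
#'   numeric RPM value applied to both samples.
#' @return data.frame with `unit_id`, `rpm_kd`, `rpm_ctrl`, `log2fc` and
#'   `total_reads` (sum of raw counts in the two samples).
#' @export
transcript_fold_change <- function(se, kd, ctrl, level = c("pas", "gene"),
                                   pseudocount = NULL) {
  level <- match.arg(level)
  stopifnot(all(c(kd, ctrl) %in% colnames(se)))
  se <- compute_rpm(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  totals <- colSums(counts)[c(kd, ctrl)]
  if (level == "pas") {
    rpm <- SummarizedExperiment::assay(se, "rpm")
    cnt <- counts
  } else {
    rpm <- gene_level_expression(se, "rpm")
    cnt <- gene_level_expression(se, "counts")
  }
  pc <- resolve_pseudocount(pseudocount, totals)
  data.frame(unit_id = rownames(rpm),
             rpm_kd = rpm[, kd], rpm_ctrl = rpm[, ctrl],
             log2fc = log2((rpm[, kd] + pc[1L]) / (rpm[, ctrl] + pc[2L])),
             total_reads = cnt[, kd] + cnt[, ctrl],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call regulated transcripts and the down/up ratio
#'
#' A unit is `down` when log2fc < -log2(fc_cutoff), `up` when above
#' +log2(fc_cutoff), both gated on `total_reads > min_total`; otherwise
#' `unchanged`. The summary down/up ratio is #down / #up; with no
#' upregulated units it is reported as infinite and flagged.
#'
#' @param fc data.frame from [transcript_fold_change].
#' @param fc_cutoff fold-change cutoff on the natural scale (default 2).
#' @param min_total exclusive minimum total read count (default 50).
#' @return the input with a `call` column; the down/up summary is in
#'   `attr(, "down_up_ratio")` (`n_down`, `n_up`, `ratio`, `infinite`).
#' @export
call_regulated_transcripts <- function(fc, fc_cutoff = 2, min_total = 50) {
  thr <- log2(fc_cutoff)
  eligible <- fc$total_reads > min_total
  call <- ifelse(eligible & fc$log2fc < -thr, "down",
                 ifelse(eligible & fc$log2fc > thr, "up", "unchanged"))
  fc$call <- factor(call, levels = c("down", "up", "unchanged"))
  n_down <- sum(fc$call == "down")
  n_up <- sum(fc$call == "up")
  attr(fc, "down_up_ratio") <- list(
    n_down = n_down, n_up = n_up,
    ratio = if (n_up == 0L) Inf else n_down / n_up,
    infinite = n_up == 0L)
  fc
}

#' Stratify genes by expression level
#'
#' Genes below the 25th percentile of the reference expression are
#' `low`, those above the 75th are `high`, and the rest `median`.
#'
#' @param ref_expr named numeric vector of reference-sample (control)
#'   gene expression.
#' @return factor with levels `low`, `median`, `high`.
#' @export
expression_strata <- function(ref_expr) {
  q <- stats::quantile(ref_expr, c(0.25, 0.75))
  factor(ifelse(ref_expr < q[1L], "low",
                ifelse(ref_expr > q[2L], "high", "median")),
         levels = c("low", "median", "high"))
}

#' Compare log2 fold-change distributions between strata
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the log2fc values of a
#' designated pair of groups (e.g. low- vs high-expression genes, or
#' mRNA vs lncRNA), plus per-group summaries.
#'
#' @param log2fc numeric vector of per-unit log2 fold changes.
#' @param group factor of the same length (expression strata, biotype,
#'   ...).
#' @param pair length-2 character vector naming the groups to test.
#' @param min_group_size groups smaller than this leave the p-value
#'   undefined with a warning (default 5).
#' @return list with `summary` (per-group n and median log2fc),
#'   `statistic` and `p_value`.
#' @export
stratified_ks <- function(log2fc, group, pair, min_group_size = 5L) {
  stopifnot(length(log2fc) == length(group), length(pair) == 2L)
  group <- as.factor(group)
  summ <- data.frame(group = levels(group),
                     n = as.integer(table(group)),
                     median_log2fc = as.numeric(
                       tapply(log2fc, group, stats::median)),
                     row.names = NULL)
  a <- log2fc[group == pair[1L]]
  b <- log2fc[group == pair[2L]]
  if (length(a) < min_group_size || length(b) < min_group_size) {
    warning("group size below ", min_group_size, "; K-S p-value undefined")
    return(list(summary = summ, statistic = NA_real_, p_value = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(summary = summ, statistic = unname(kt$statistic),
       p_value = kt$p.value)
}

#' Hierarchically cluster samples by fold-change profiles
#'
#' Distance between samples is 1 - Pearson correlation of their log2
#' fold-change vectors; average linkage. Constant columns (undefined
#' correlation) are dropped with a warning.
#'
#' @param fc_matrix numeric matrix, units x samples (at least 2 columns).
#' @return an `hclust` object.
#' @export
cluster_samples <- function(fc_matrix) {
  stopifnot(is.matrix(fc_matrix))
  keep <- apply(fc_matrix, 2L, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning("dropping constant sample column(s): ",
            paste(colnames(fc_matrix)[!keep], collapse = ", "))
    fc_matrix <- fc_matrix[, keep, drop = FALSE]
  }
  if (ncol(fc_matrix) < 2L) stop("need at least 2 non-constant samples")
  d <- stats::as.dist(1 - stats::cor(fc_matrix, method = "pearson"))
  stats::hclust(d, method = "average")
}
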
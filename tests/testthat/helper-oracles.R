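# Independent oracles and small fixture builders shared across tests.

# Brute-force greedy clustering: repeatedly pick the unclustered site with
# the most pooled reads (ties: 5'-most in transcript orientation) and
# absorb everything within the window. Deliberately naive re-scan each
# round; used to check cluster_cleavage_sites.
oracle_cluster <- function(pos, count, strand = "+", window = 24L) {
  unassigned <- rep(TRUE, length(pos))
  out <- integer(length(pos))       # representative position per site
  while (any(unassigned)) {
    idx <- which(unassigned)
    best <- idx[1L]
    for (i in idx) {
      better <- count[i] > count[best] ||
        (count[i] == count[best] &&
           (if (strand == "+") pos[i] < pos[best] else pos[i] > pos[best]))
      if (better) best <- i
    }
    members <- idx[abs(pos[idx] - pos[best]) <= window]
    out[members] <- pos[best]
    unassigned[members] <- FALSE
  }
  out
}

# Two-sided Fisher exact p for a 2x2 table by explicit enumeration of the
# conditional distribution with log-factorial arithmetic (independent of
# both stats::fisher.test and the package implementation).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  lo <- max(0L, k - m2); hi <- min(k, m1)
  logp <- function(x) {
    lfactorial(m1) - lfactorial(x) - lfactorial(m1 - x) +
      lfactorial(m2) - lfactorial(k - x) - lfactorial(m2 - (k - x)) -
      (lfactorial(n) - lfactorial(k) - lfactorial(n - k))
  }
  pr <- exp(vapply(lo:hi, logp, numeric(1)))
  sum(pr[pr <= exp(logp(a)) * (1 + 1e-7)])
}

# A small fully simulated dataset reused by several files.
small_config <- function(seed = 401L, ...) {
  sim_config(n_genes = 25L, n_reads = 6000L, expr_sd_log2 = 0.5,
             seed = seed, ...)
}

# Convert simulated read truth directly into AlignedReadRecord rows,
# bypassing SAM serialization (exercised separately).
records_from_reads <- function(reads) {
  L <- as.integer(sub("M.*", "", sub("^\\d+S", "", reads$cigar)))
  rev <- bitwAnd(reads$flag, 16L) > 0L
  data.frame(read_id = reads$qname, contig = reads$contig,
             start0 = reads$pos0, end0 = reads$pos0 + L,
             strand = ifelse(rev, "-", "+"), mapq = reads$mapq,
             clip5_len = reads$tail_k,
             clip5_bases = strrep("T", reads$tail_k),
             clip_sam = ifelse(rev, strrep("A", reads$tail_k),
                               strrep("T", reads$tail_k)),
             unique = TRUE, stringsAsFactors = FALSE)
}

# Run the call -> tally -> atlas -> filter chain on a simulated fixture.
atlas_from_fixture <- function(fx, window = 24L, min_reads = 2L,
                               min_frac = 0.05) {
  events <- do.call(rbind, lapply(names(fx$reads), function(s) {
    identify_pass_reads(records_from_reads(fx$reads[[s]]),
                        fx$assets$genome, s)$events
  }))
  cl <- cluster_cleavage_sites(tally_cleavage_sites(events), window = window)
  cl <- annotate_pas_location(cl, fx$assets$annotation)
  filter_pas_clusters(cl, min_reads = min_reads, min_frac = min_frac)
}

# A hand-built SummarizedExperiment for quantification/APA tests.
toy_se <- function(counts, gene_id, region = NULL, strand = "+",
                   position = NULL, biotype = NULL) {
  n <- nrow(counts)
  cl <- list(
    clusters = data.frame(
      cluster_id = rownames(counts), contig = "c", strand = strand,
      position = if (is.null(position)) seq_len(n) * 1000L else position,
      n_sites = 1L, count = rowSums(counts), gene_id = gene_id,
      biotype = if (is.null(biotype)) "mRNA" else biotype,
      region = if (is.null(region)) "three_prime_region" else region,
      stringsAsFactors = FALSE),
    counts = data.frame(
      cluster_id = rep(rownames(counts), ncol(counts)),
      sample_id = rep(colnames(counts), each = nrow(counts)),
      count = as.vector(counts), stringsAsFactors = FALSE))
  class(cl) <- "pas_clusters"
  pas_count_table(cl, samples = colnames(counts))
}

# Fully conserved PFM with the given consensus (DNA or RNA letters).
conserved_pfm <- function(consensus) {
  letters4 <- c("A", "C", "G", "U")
  idx <- match(strsplit(chartr("T", "U", consensus), "")[[1L]], letters4)
  m <- matrix(0, length(idx), 4L, dimnames = list(NULL, letters4))
  m[cbind(seq_along(idx), idx)] <- 1
  pfm(m)
}

uniform_pfm <- function(width = 7L) {
  pfm(matrix(0.25, width, 4L,
             dimnames = list(NULL, c("A", "C", "G", "U"))))
}
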
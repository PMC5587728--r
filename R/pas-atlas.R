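#' PAS atlas construction
#'
#' Cleavage events are heterogeneous at single-nucleotide resolution, so
#' nearby sites are clustered into poly(A) sites (PASs): sites within 24
#' nt are iteratively grouped, the member with the most pooled PASS reads
#' becomes the cluster's representative position, and clusters are kept
#' only when supported by at least two PASS reads that also account for
#' more than 5% of their gene's reads in at least one sample. Each
#' retained PAS is annotated with its gene, its region (3'-most exon plus
#' downstream extension, or upstream) and its poly(A)-signal class.
#'
#' @name pas_atlas
NULL

# Default single-nucleotide variants of the canonical AAUAAA hexamer.
PAS_SIGNAL_VARIANTS <- c("AUUAAA", "UAUAAA", "AGUAAA", "AAGAAA", "AAUAUA",
                         "AAUACA", "CAUAAA", "GAUAAA", "AAUGAA", "ACUAAA")

#' Cluster cleavage sites into PASs
#'
#' Greedy iterative clustering per contig and strand: repeatedly take the
#' unclustered site with the highest pooled count (ties broken by the
#' 5'-most position in transcript orientation), absorb every unclustered
#' site within `window` nt of it, and mark it the representative. The
#' procedure is deterministic.
#'
#' @param tally data.frame from [tally_cleavage_sites].
#' @param window maximum distance (nt) from a representative to its
#'   members; default 24.
#' @return list of class `pas_clusters` with `clusters` (`cluster_id`,
#'   `contig`, `strand`, `position` of the representative, `n_sites`,
#'   pooled `count`), `sites` (per-site cluster membership) and `counts`
#'   (long per-cluster per-sample counts).
#' @export
cluster_cleavage_sites <- function(tally, window = 24L) {
  if (window < 0L) stop("window must be non-negative")
  dt <- data.table::as.data.table(tally)
  pooled <- as.data.frame(dt[, list(count = sum(count)),
                             by = c("contig", "strand", "position")])
  if (nrow(pooled) == 0L) {
    empty <- data.frame(cluster_id = character(0), contig = character(0),
                        strand = character(0), position = integer(0),
                        n_sites = integer(0), count = integer(0),
                        stringsAsFactors = FALSE)
    return(structure(list(clusters = empty,
                          sites = cbind(pooled, cluster_id = character(0)),
                          counts = data.frame(cluster_id = character(0),
                                              sample_id = character(0),
                                              count = integer(0))),
                     class = "pas_clusters"))
  }
  pooled$cluster_id <- NA_character_
  pooled$rep_position <- NA_integer_
  groups <- split(seq_len(nrow(pooled)),
                  paste(pooled$contig, pooled$strand))
  for (g in groups) {
    pos <- pooled$position[g]
    cnt <- pooled$count[g]
    five_prime <- if (pooled$strand[g[1L]] == "+") pos else -pos
    ord <- order(-cnt, five_prime)
    assigned <- logical(length(g))
    for (i in ord) {
      if (assigned[i]) next
      members <- !assigned & abs(pos - pos[i]) <= window
      assigned[members] <- TRUE
      pooled$cluster_id[g[members]] <- sprintf(
        "%s:%d:%s", pooled$contig[g[i]], pos[i], pooled$strand[g[i]])
      pooled$rep_position[g[members]] <- pos[i]
    }
  }
  sdt <- data.table::as.data.table(pooled)
  clusters <- as.data.frame(sdt[, list(
    contig = contig[1L], strand = strand[1L], position = rep_position[1L],
    n_sites = length(position), count = sum(count)), by = "cluster_id"])
  clusters <- clusters[order(clusters$contig, clusters$position,
                             clusters$strand),
                       c("cluster_id", "contig", "strand", "position",
                         "n_sites", "count")]
  rownames(clusters) <- NULL
  cdt <- data.table::as.data.table(
    merge(tally, pooled[, c("contig", "strand", "position", "cluster_id")],
          by = c("contig", "strand", "position")))
  counts <- as.data.frame(cdt[, list(count = sum(count)),
                              by = c("cluster_id", "sample_id")])
  structure(list(clusters = clusters,
                 sites = pooled[, c("contig", "strand", "position", "count",
                                    "cluster_id")],
                 counts = counts),
            class = "pas_clusters")
}

#' Assign PAS clusters to genes and regions
#'
#' A cluster is assigned to a gene when its representative position lies
#' on the gene's strand within the gene span, or within `extension` nt
#' downstream of the gene's 3' end (span matches win over extension
#' matches; among extension candidates the nearest 3' end wins). The
#' region is `three_prime_region` when the position falls in the 3'-most
#' exon or the downstream extension, `upstream` otherwise. Unassigned
#' clusters keep `NA` gene ids and are excluded from gene-level
#' statistics downstream.
#'
#' @param clusters a `pas_clusters` object.
#' @param annotation gene table (0-based half-open coordinates) with
#'   columns `gene_id`, `contig`, `strand`, `gene_start`, `gene_end`,
#'   `last_exon_start`, `last_exon_end`, `biotype`.
#' @param extension downstream extension in nt (default 4000).
#' @return the `pas_clusters` object with `gene_id`, `region` and
#'   `biotype` columns added to `$clusters`.
#' @export
annotate_pas_location <- function(clusters, annotation, extension = 4000L) {
  cl <- clusters$clusters
  pas_gr <- GenomicRanges::GRanges(cl$contig,
                                   IRanges::IRanges(cl$position + 1L,
                                                    width = 1L),
                                   strand = cl$strand)
  gene_gr <- GenomicRanges::GRanges(annotation$contig,
                                    IRanges::IRanges(annotation$gene_start + 1L,
                                                     annotation$gene_end),
                                    strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(pas_gr, gene_gr)
  gene_idx <- rep(NA_integer_, nrow(cl))
  gene_idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  plus <- annotation$strand == "+"
  ext_start <- ifelse(plus, annotation$gene_end + 1L,
                      annotation$gene_start - extension + 1L)
  ext_gr <- GenomicRanges::GRanges(annotation$contig,
                                   IRanges::IRanges(ext_start,
                                                    width = extension),
                                   strand = annotation$strand)
  todo <- which(is.na(gene_idx))
  if (length(todo)) {
    eh <- GenomicRanges::findOverlaps(pas_gr[todo], ext_gr)
    if (length(eh)) {
      q <- S4Vectors::queryHits(eh)
      s <- S4Vectors::subjectHits(eh)
      end3 <- ifelse(plus, annotation$gene_end - 1L, annotation$gene_start)
      d <- abs(cl$position[todo[q]] - end3[s])
      best <- tapply(seq_along(q), q, function(ii) ii[which.min(d[ii])])
      gene_idx[todo[as.integer(names(best))]] <- s[unlist(best)]
    }
  }

  cl$gene_id <- annotation$gene_id[gene_idx]
  cl$biotype <- annotation$biotype[gene_idx]
  in_ext <- !is.na(gene_idx) & ifelse(
    plus[gene_idx],
    cl$position >= annotation$gene_end[gene_idx],
    cl$position < annotation$gene_start[gene_idx])
  in_last <- !is.na(gene_idx) &
    cl$position >= annotation$last_exon_start[gene_idx] &
    cl$position < annotation$last_exon_end[gene_idx]
  cl$region <- ifelse(is.na(gene_idx), NA_character_,
                      ifelse(in_last | in_ext, "three_prime_region",
                             "upstream"))
  clusters$clusters <- cl
  clusters
}

#' Filter PAS clusters on read support and relative abundance
#'
#' A cluster is retained iff there exists a sample in which it has at
#' least `min_reads` PASS reads *and* those reads exceed `min_frac` of
#' all PASS reads assigned to its gene in that same sample. Clusters
#' without a gene assignment cannot qualify and are dropped. Relaxing
#' either threshold can only grow the retained set.
#'
#' @param clusters an annotated `pas_clusters` object (see
#'   [annotate_pas_location]).
#' @param min_reads minimum PASS reads in the qualifying sample
#'   (default 2).
#' @param min_frac minimum relative abundance within the gene in the
#'   qualifying sample, exclusive bound (default 0.05).
#' @return the `pas_clusters` object restricted to retained clusters.
#' @export
filter_pas_clusters <- function(clusters, min_reads = 2L, min_frac = 0.05) {
  cl <- clusters$clusters
  if (!"gene_id" %in% names(cl)) {
    stop("clusters must be annotated with genes first ",
         "(see annotate_pas_location)")
  }
  cts <- merge(clusters$counts, cl[, c("cluster_id", "gene_id")],
               by = "cluster_id")
  cts <- cts[!is.na(cts$gene_id), , drop = FALSE]
  if (nrow(cts)) {
    dt <- data.table::as.data.table(cts)
    dt[, gene_total := sum(count), by = c("gene_id", "sample_id")]
    dt[, ok := count >= min_reads & gene_total > 0L &
         count / gene_total > min_frac]
    keep_ids <- unique(dt$cluster_id[dt$ok])
  } else {
    keep_ids <- character(0)
  }
  keep <- cl$cluster_id %in% keep_ids
  clusters$clusters <- cl[keep, , drop = FALSE]
  rownames(clusters$clusters) <- NULL
  clusters$sites <- clusters$sites[
    clusters$sites$cluster_id %in% keep_ids, , drop = FALSE]
  clusters$counts <- clusters$counts[
    clusters$counts$cluster_id %in% keep_ids, , drop = FALSE]
  clusters
}

#' Classify the poly(A) signal of PAS upstream flanks
#'
#' Hierarchical classification of the 40 nt upstream of the cleavage site
#' (transcript orientation): `AAUAAA` when the canonical hexamer is
#' present; otherwise `variant` when any of the configured
#' single-nucleotide variants is present; otherwise `A_rich` when some
#' hexamer window contains five or more As; otherwise `none`.
#'
#' @param flank character vector of upstream flanks (nominally 40 nt;
#'   shorter allowed at contig edges). U and T are equivalent.
#' @param variants variant hexamers (RNA or DNA alphabet).
#' @param a_rich_min minimum As in a hexamer for the A-rich class.
#' @return factor with levels `AAUAAA`, `variant`, `A_rich`, `none`.
#' @export
classify_pas_signal <- function(flank, variants = PAS_SIGNAL_VARIANTS,
                                a_rich_min = 5L) {
  x <- as_dna(flank)
  if (any(grepl("[^ACGT]", x))) {
    stop("flanks contain characters outside the A/C/G/T/U alphabet")
  }
  vd <- chartr("U", "T", variants)
  has_canon <- grepl("AATAAA", x, fixed = TRUE)
  has_var <- Reduce(`|`, lapply(vd, function(v) grepl(v, x, fixed = TRUE)))
  a_rich <- vapply(x, function(s) {
    n <- nchar(s)
    if (n < 6L) return(FALSE)
    isa <- cumsum(c(0L, strsplit(s, "")[[1L]] == "A"))
    any(isa[7:(n + 1L)] - isa[1:(n - 5L)] >= a_rich_min)
  }, logical(1), USE.NAMES = FALSE)
  factor(ifelse(has_canon, "AAUAAA",
                ifelse(has_var, "variant",
                       ifelse(a_rich, "A_rich", "none"))),
         levels = c("AAUAAA", "variant", "A_rich", "none"))
}

#' Annotate PAS clusters with their poly(A)-signal class
#'
#' Extracts the -40..-1 upstream flank of each representative position
#' and applies [classify_pas_signal].
#'
#' @param clusters a `pas_clusters` object.
#' @param genome named `DNAStringSet`.
#' @inheritParams classify_pas_signal
#' @return the `pas_clusters` object with a `signal_class` column.
#' @export
annotate_pas_signal <- function(clusters, genome,
                                variants = PAS_SIGNAL_VARIANTS,
                                a_rich_min = 5L) {
  cl <- clusters$clusters
  fl <- pas_flanks(genome, cl, upstream = 40L, downstream = 0L)
  # pas_flank spans -40..0; the signal region excludes the cleavage base
  fl <- substr(fl, 1L, pmax(nchar(fl) - 1L, 0L))
  clusters$clusters$signal_class <- classify_pas_signal(fl, variants,
                                                        a_rich_min)
  clusters
}

#' Write a PAS atlas as BED6
#'
#' One line per retained cluster: `chrom`, 0-based `start` at the
#' representative position, `end = start + 1`, `name` as
#' `gene_id|cluster_id`, `score` = pooled PASS count, `strand`.
#'
#' @param clusters a `pas_clusters` object.
#' @param path destination path.
#' @export
write_pas_bed <- function(clusters, path) {
  cl <- clusters$clusters
  gene <- if ("gene_id" %in% names(cl)) ifelse(is.na(cl$gene_id), ".",
                                               cl$gene_id) else "."
  bed <- data.frame(cl$contig, cl$position, cl$position + 1L,
                    paste0(gene, "|", cl$cluster_id), cl$count, cl$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
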
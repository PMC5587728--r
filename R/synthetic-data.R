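#' Synthetic 3' end sequencing data
#'
#' Generates a toy genome, gene annotation, ground-truth PAS usage table
#' and SAM-format 3' end reads with the statistical structure the
#' downstream analysis assumes: multi-PAS gene architectures (3'UTR plus
#' optional upstream-region PASs), per-condition usage proportions with
#' planted knockdown effects, gene expression spanning low/median/high
#' strata, poly(A)-derived non-genomic 5' T stretches of variable length,
#' MAPQ noise, and consensus motif matches planted upstream of a subset of
#' PASs. Every quantity is driven by a single seed, so fixtures are
#' byte-reproducible.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_genes number of genes to simulate.
#' @param conditions character vector of condition labels; the first is
#'   treated as the control when planting effects.
#' @param n_reads reads simulated per sample.
#' @param read_length sequenced read length in nt.
#' @param utr_pas_weights sampling weights for the number of 3'UTR PASs
#'   per gene; element `i` is the weight of `i` PASs (max 3).
#' @param ur_pas_frac fraction of genes carrying an additional
#'   upstream-region (intronic) PAS.
#' @param ur_usage baseline usage proportion of the upstream-region PAS
#'   where present.
#' @param frac_shifted fraction of genes with a planted distal-usage shift
#'   in the non-control conditions.
#' @param shift_log2 planted log2 shift of distal-PAS usage (negative =
#'   distal usage down, i.e. 3'UTR shortening in the knockdown).
#' @param expr_shift_frac fraction of genes with a planted gene-expression
#'   shift in the non-control conditions.
#' @param expr_shift_log2 magnitude (log2) of the planted expression shift.
#' @param expr_down_prop of expression-shifted genes, the proportion
#'   shifted down (the rest are shifted up).
#' @param expr_sd_log2 standard deviation (log2) of gene expression
#'   levels; 0 gives equal expression.
#' @param lncrna_frac fraction of genes labelled lncRNA (the rest mRNA).
#' @param tail_geom_p geometric success probability for the number of
#'   non-genomic tail Ts per read; the default puts about 10% of reads
#'   below the 2-T threshold used by PASS calling.
#' @param tail_max maximum simulated tail length.
#' @param jitter maximum cleavage-site jitter in nt; realized offsets are
#'   symmetric binomial on `-jitter..jitter`.
#' @param mapq_low_frac fraction of reads drawn with MAPQ <= 10.
#' @param motif_frac fraction of PASs with a planted PFM-consensus 7-mer
#'   in the -100..-47 window (start positions) upstream of the cleavage
#'   site.
#' @param pfm a [pfm] object whose consensus is planted; default is the
#'   bundled synthetic AUA-like matrix.
#' @param extension downstream extension (nt) used when sizing the contig
#'   and annotating PAS regions.
#' @param contig_length optional fixed contig length; an error is raised
#'   if it cannot hold the requested genes.
#' @param read_orientation `"reverse"` (default; reads are reverse
#'   complements of transcript 3' ends, carrying the poly(A) tail as 5'
#'   Ts) or `"forward"` (sense reads with trailing As), for exploring
#'   alternative library conventions.
#' @param seed integer seed; mandatory.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       conditions = c("ctrl", "kd"),
                       n_reads = 125000L,
                       read_length = 100L,
                       utr_pas_weights = c(0, 1),
                       ur_pas_frac = 0.3,
                       ur_usage = 0.15,
                       frac_shifted = 0.3,
                       shift_log2 = -1.5,
                       expr_shift_frac = 0,
                       expr_shift_log2 = 1,
                       expr_down_prop = 0.5,
                       expr_sd_log2 = 1.25,
                       lncrna_frac = 0.2,
                       tail_geom_p = 1 - sqrt(0.9),
                       tail_max = 30L,
                       jitter = 2L,
                       mapq_low_frac = 0.05,
                       motif_frac = 0.1,
                       pfm = NULL,
                       extension = 4000L,
                       contig_length = NULL,
                       read_orientation = c("reverse", "forward"),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  read_orientation <- match.arg(read_orientation)
  fracs <- c(ur_pas_frac = ur_pas_frac, frac_shifted = frac_shifted,
             expr_shift_frac = expr_shift_frac, expr_down_prop = expr_down_prop,
             lncrna_frac = lncrna_frac, mapq_low_frac = mapq_low_frac,
             motif_frac = motif_frac, ur_usage = ur_usage,
             tail_geom_p = tail_geom_p)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) stop("fractions out of [0,1]: ",
                     paste(names(fracs)[bad], collapse = ", "))
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length(conditions) < 1L) stop("at least one condition is required")
  if (is.null(pfm)) pfm <- read_pfm(system.file("extdata",
    "starpap_like_pfm_synthetic.tsv", package = "apatlas", mustWork = TRUE))
  cfg <- list(n_genes = as.integer(n_genes), conditions = conditions,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              utr_pas_weights = utr_pas_weights, ur_pas_frac = ur_pas_frac,
              ur_usage = ur_usage, frac_shifted = frac_shifted,
              shift_log2 = shift_log2, expr_shift_frac = expr_shift_frac,
              expr_shift_log2 = expr_shift_log2,
              expr_down_prop = expr_down_prop, expr_sd_log2 = expr_sd_log2,
              lncrna_frac = lncrna_frac, tail_geom_p = tail_geom_p,
              tail_max = as.integer(tail_max), jitter = as.integer(jitter),
              mapq_low_frac = mapq_low_frac, motif_frac = motif_frac,
              pfm = pfm, extension = as.integer(extension),
              contig_length = contig_length,
              read_orientation = read_orientation, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Geometry of a simulated gene (transcript coordinates, nt).
SIM_GENE_LEN <- 2500L
SIM_GAP <- 600L
SIM_MARGIN <- 400L
SIM_LAST_EXON_LEN <- 1000L

#' Build a toy genome and annotation
#'
#' Lays out non-overlapping genes on a single contig with random ACGT
#' sequence, places 1-3 PASs in each gene's 3'-most exon plus an optional
#' upstream-region PAS, plants the PFM consensus upstream of a configured
#' fraction of PASs, and guarantees that the transcript-sense base
#' immediately downstream of every possible cleavage position is not an A
#' (so simulated tails are unambiguously non-genomic).
#'
#' @param config a [sim_config].
#' @return a list of class `genome_assets` with elements `genome` (a named
#'   `DNAStringSet`), `annotation` (gene table with 0-based half-open
#'   coordinates) and `pas_table` (one row per true PAS: genomic position
#'   of the last transcribed nucleotide, region label, planted-motif
#'   flag).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  slot <- SIM_GENE_LEN + SIM_GAP
  need <- 2L * SIM_MARGIN + n * slot
  len <- if (is.null(config$contig_length)) need else as.integer(config$contig_length)
  if (len < need) {
    stop("contig_length ", len, " too small for ", n, " genes (need ", need, ")")
  }
  contig <- "chrS"
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)

  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- ifelse(stats::runif(n) < config$lncrna_frac, "lncRNA", "mRNA")
  g0 <- SIM_MARGIN + (seq_len(n) - 1L) * slot         # 0-based gene start
  g1 <- g0 + SIM_GENE_LEN                             # half-open end

  m_utr <- sample(seq_along(config$utr_pas_weights), n, replace = TRUE,
                  prob = config$utr_pas_weights)
  if (any(m_utr > 3L)) stop("at most 3 3'UTR PASs per gene are supported")
  has_ur <- stats::runif(n) < config$ur_pas_frac

  cons <- pfm_consensus(config$pfm, "DNA")
  w <- nchar(cons)
  jmax <- config$jitter

  # Write a transcript-sense base patch into the plus-strand base vector.
  put_tx <- function(gi, tx_pos, patch) {
    if (strand[gi] == "+") {
      bases[g0[gi] + tx_pos + 1L] <<- patch
    } else {
      # transcript coord t maps to 0-based genomic g1-1-t; complement the
      # transcript-sense patch onto the plus strand, elementwise
      bases[g1[gi] - tx_pos] <<- chartr("ACGT", "TGCA", patch)
    }
  }

  pas_rows <- vector("list", n)
  for (gi in seq_len(n)) {
    m <- m_utr[gi]
    step <- if (m > 1L) 300L else 0L
    tx <- (SIM_GENE_LEN - 150L) - step * rev(seq_len(m) - 1L) +
      sample(-40L:40L, m, replace = TRUE)
    region <- rep("three_prime_exon", m)
    if (has_ur[gi]) {
      tx <- c(1250L + sample(-50L:50L, 1L), tx)
      region <- c("upstream", region)
    }
    planted <- stats::runif(length(tx)) < config$motif_frac
    for (k in seq_along(tx)) {
      # keep the first base past any jittered cleavage site non-A
      patch_at <- (tx[k] - jmax):(tx[k] + jmax + 1L)
      put_tx(gi, patch_at, sample(c("C", "G", "T"), length(patch_at),
                                  replace = TRUE))
      if (planted[k]) {
        start <- sample(-100L:-47L, 1L)               # window stays in -100..-41
        put_tx(gi, (tx[k] + start):(tx[k] + start + w - 1L),
               strsplit(cons, "")[[1]])
      }
    }
    genomic <- if (strand[gi] == "+") g0[gi] + tx else g1[gi] - 1L - tx
    pas_rows[[gi]] <- data.frame(
      gene_id = sprintf("gene%04d", gi), pas_id = sprintf("gene%04d.p%d", gi,
                                                          seq_along(tx)),
      contig = contig, strand = strand[gi], position = genomic, tx_pos = tx,
      region = region, motif_planted = planted, rank = seq_along(tx),
      stringsAsFactors = FALSE)
  }

  # last exon: final SIM_LAST_EXON_LEN nt in transcript orientation
  le0 <- ifelse(strand == "+", g1 - SIM_LAST_EXON_LEN, g0)
  le1 <- ifelse(strand == "+", g1, g0 + SIM_LAST_EXON_LEN)
  annotation <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)), contig = contig,
    strand = strand, gene_start = g0, gene_end = g1,
    last_exon_start = le0, last_exon_end = le1, biotype = biotype,
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(structure(paste(bases, collapse = ""),
                                               names = contig))
  assets <- list(genome = genome, annotation = annotation,
                 pas_table = do.call(rbind, pas_rows), config = config)
  class(assets) <- "genome_assets"
  assets
}

#' Plan ground-truth expression and PAS usage
#'
#' Samples per-gene expression levels spanning low/median/high strata,
#' assigns baseline PAS usage proportions, and plants the configured
#' usage and expression shifts in the non-control conditions. For a gene
#' with a planted usage shift, the 3'-most (distal) 3'UTR PAS has its
#' usage multiplied by `2^shift_log2` and the gene's proportions are
#' renormalized, which shifts the distal/proximal log2 usage ratio by
#' exactly `shift_log2`.
#'
#' @param assets a `genome_assets` object from [build_toy_genome].
#' @param config a [sim_config] (defaults to the one stored in `assets`).
#' @return a list of class `truth_table` with `genes` (per-gene expected
#'   RPM per condition, biotype, planted directions) and `usage` (per-PAS
#'   usage proportion per condition; proportions sum to 1 within each
#'   gene and condition).
#' @export
plan_truth <- function(assets, config = assets$config) {
  stopifnot(inherits(assets, "genome_assets"))
  set.seed(derive_seed(config$seed, 2L))
  ann <- assets$annotation
  pas <- assets$pas_table
  n <- nrow(ann)
  conds <- config$conditions
  ctrl <- conds[1L]

  n_shift <- round(config$frac_shifted * n)
  shifted <- sort(sample.int(n, n_shift))
  apa_dir <- rep("none", n)
  apa_dir[shifted] <- if (config$shift_log2 < 0) "down" else
    if (config$shift_log2 > 0) "up" else "none"

  n_eshift <- round(config$expr_shift_frac * n)
  eshifted <- sort(sample.int(n, n_eshift))
  e_dir <- rep("none", n)
  if (n_eshift > 0L) {
    n_down <- round(config$expr_down_prop * n_eshift)
    e_dir[eshifted] <- c(rep("down", n_down), rep("up", n_eshift - n_down))
  }

  weight <- 2^stats::rnorm(n, 0, config$expr_sd_log2)
  expr <- matrix(NA_real_, n, length(conds),
                 dimnames = list(ann$gene_id, conds))
  for (cd in conds) {
    wc <- weight
    if (cd != ctrl) {
      wc[e_dir == "down"] <- wc[e_dir == "down"] * 2^(-config$expr_shift_log2)
      wc[e_dir == "up"] <- wc[e_dir == "up"] * 2^(config$expr_shift_log2)
    }
    expr[, cd] <- wc / sum(wc) * 1e6
  }

  # baseline usage: upstream PAS gets ur_usage, 3'UTR PASs share the rest
  base <- numeric(nrow(pas))
  for (g in split(seq_len(nrow(pas)), pas$gene_id)) {
    is_ur <- pas$region[g] == "upstream"
    u <- numeric(length(g))
    u[is_ur] <- config$ur_usage
    u[!is_ur] <- (1 - sum(u[is_ur])) / sum(!is_ur)
    base[g] <- u
  }

  usage <- data.frame(pas[, c("gene_id", "pas_id", "region", "rank")],
                      stringsAsFactors = FALSE)
  shifted_ids <- ann$gene_id[shifted]
  # distal = 3'-most 3'UTR PAS = highest rank (ranks are 5'->3')
  is_distal <- stats::ave(ifelse(pas$region == "upstream", -1L, pas$rank),
                          pas$gene_id, FUN = max) == pas$rank &
    pas$region != "upstream"
  for (cd in conds) {
    u <- base
    if (cd != ctrl && n_shift > 0L) {
      hit <- pas$gene_id %in% shifted_ids & is_distal
      u[hit] <- u[hit] * 2^config$shift_log2
      if (any(u < 0)) {
        warning("usage proportions clamped to [0,1] after shift")
        u <- pmax(u, 0)
      }
      tot <- stats::ave(u, pas$gene_id, FUN = sum)
      u <- u / tot
    }
    usage[[paste0("usage_", cd)]] <- u
  }

  genes <- data.frame(gene_id = ann$gene_id, biotype = ann$biotype,
                      apa_direction = apa_dir, expr_direction = e_dir,
                      stringsAsFactors = FALSE)
  for (cd in conds) genes[[paste0("expr_", cd)]] <- expr[, cd]
  truth <- list(genes = genes, usage = usage, conditions = conds)
  class(truth) <- "truth_table"
  truth
}

#' Simulate one sample of aligned 3' end reads
#'
#' Each read picks a gene proportionally to its expression in `condition`,
#' a PAS by the gene's usage proportions, a jittered cleavage position, a
#' geometric non-genomic tail length and a MAPQ value, then is emitted as
#' an aligned SAM-style record. Under the default reverse orientation a
#' read from a plus-strand gene aligns to the minus genome strand with the
#' tail appearing as a trailing soft-clipped A-stretch in SAM orientation
#' (leading soft-clipped Ts for minus-strand genes).
#'
#' @param assets a `genome_assets` object.
#' @param truth a `truth_table` from [plan_truth].
#' @param condition condition label to simulate.
#' @param n_reads number of reads (default from the config).
#' @param seed integer seed for this sample.
#' @param config a [sim_config].
#' @return a data.frame with one row per read: SAM fields (`qname`,
#'   `flag`, `contig`, `pos0`, `mapq`, `cigar`, `seq`) plus ground-truth
#'   columns (`gene_id`, `pas_id`, `cleavage_pos`, `tail_k`).
#' @export
simulate_sample_reads <- function(assets, truth, condition,
                                  n_reads = NULL, seed,
                                  config = assets$config) {
  stopifnot(inherits(assets, "genome_assets"), inherits(truth, "truth_table"))
  if (!condition %in% truth$conditions) {
    stop("unknown condition '", condition, "'")
  }
  if (is.null(n_reads)) n_reads <- config$n_reads
  if (n_reads < 1L) stop("n_reads must be >= 1")
  set.seed(seed)

  ann <- assets$annotation
  pas <- assets$pas_table
  usage <- truth$usage[[paste0("usage_", condition)]]
  expr <- truth$genes[[paste0("expr_", condition)]]

  gene_idx <- sample.int(nrow(ann), n_reads, replace = TRUE, prob = expr)
  pas_row <- integer(n_reads)
  pas_by_gene <- split(seq_len(nrow(pas)), factor(pas$gene_id, ann$gene_id))
  for (gi in unique(gene_idx)) {
    sel <- which(gene_idx == gi)
    rows <- pas_by_gene[[gi]]
    pas_row[sel] <- if (length(rows) == 1L) rows else
      rows[sample.int(length(rows), length(sel), replace = TRUE,
                      prob = usage[rows])]
  }

  jmax <- config$jitter
  off <- stats::rbinom(n_reads, 2L * jmax, 0.5) - jmax
  k <- pmin(stats::rgeom(n_reads, config$tail_geom_p),
            min(config$tail_max, config$read_length - 20L))
  low <- stats::runif(n_reads) < config$mapq_low_frac
  mapq <- ifelse(low, sample(0:10, n_reads, replace = TRUE),
                 sample(30:42, n_reads, replace = TRUE))

  strand <- pas$strand[pas_row]
  p_nom <- pas$position[pas_row]
  # jitter in transcript orientation: positive offsets move 3'
  p_c <- ifelse(strand == "+", p_nom + off, p_nom - off)
  L <- config$read_length - k

  contig <- pas$contig[1L]
  contig_seq <- as.character(assets$genome[[contig]])

  # SAM stores plus-strand sequence either way; the tail of a plus-strand
  # gene is a trailing A-stretch and that of a minus-strand gene a leading
  # T-stretch. The library convention only decides which alignment strand
  # (FLAG 0x10) the record carries.
  plus_gene <- strand == "+"
  pos0 <- ifelse(plus_gene, p_c - L + 1L, p_c)
  frag <- substring(contig_seq, pos0 + 1L, pos0 + L)
  seqs <- ifelse(plus_gene,
                 paste0(frag, strrep("A", k)),
                 paste0(strrep("T", k), frag))
  cigar <- ifelse(k > 0L,
                  ifelse(plus_gene, paste0(L, "M", k, "S"),
                         paste0(k, "S", L, "M")),
                  paste0(L, "M"))
  flag <- if (config$read_orientation == "reverse") {
    ifelse(plus_gene, 16L, 0L)
  } else {
    ifelse(plus_gene, 0L, 16L)
  }

  data.frame(
    qname = sprintf("%s_r%07d", condition, seq_len(n_reads)),
    flag = flag, contig = contig, pos0 = pos0, mapq = mapq, cigar = cigar,
    seq = seqs, gene_id = pas$gene_id[pas_row], pas_id = pas$pas_id[pas_row],
    cleavage_pos = p_c, tail_k = k, stringsAsFactors = FALSE)
}

#' Write a SAM file from simulated read records
#'
#' @param reads a data.frame from [simulate_sample_reads].
#' @param genome the `DNAStringSet` the reads were simulated from (for
#'   `@SQ` header lines).
#' @param path destination path.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 reads$qname, reads$flag, reads$contig, reads$pos0 + 1L,
                 reads$mapq, reads$cigar, reads$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a complete fixture bundle to disk
#'
#' Writes the genome FASTA, annotation TSV, per-sample SAM files, a
#' ground-truth TSV and a YAML config snapshot, and returns a manifest
#' with MD5 checksums, so identical seeds yield identical bundles.
#'
#' @param assets a `genome_assets` object.
#' @param truth a `truth_table`.
#' @param reads named list of read data.frames (one per sample).
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config].
#' @return data.frame manifest (`file`, `md5`), invisibly the paths too.
#' @export
write_fixture_bundle <- function(assets, truth, reads, out_dir,
                                 config = assets$config) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  p <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(assets$genome, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "annotation.tsv")
  utils::write.table(assets$annotation, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  truth_tab <- merge(merge(assets$pas_table, truth$usage[, setdiff(
    names(truth$usage), c("region", "rank"))], by = c("gene_id", "pas_id")),
    truth$genes, by = "gene_id")
  truth_tab <- truth_tab[order(truth_tab$gene_id, truth_tab$rank), ]
  p <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth_tab, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  for (s in names(reads)) {
    p <- file.path(out_dir, paste0(s, ".sam"))
    write_sam(reads[[s]], assets$genome, p)
    paths <- c(paths, p)
  }

  snap <- config
  snap$pfm <- NULL
  snap$pfm_consensus <- pfm_consensus(config$pfm)
  p <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(snap), p)
  paths <- c(paths, p)

  data.frame(file = basename(paths),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete fixture in memory
#'
#' Convenience wrapper: builds the genome, plans truth, and simulates one
#' sample per condition (sample ids equal condition labels).
#'
#' @param config a [sim_config].
#' @return list with `assets`, `truth` and `reads` (named list of per-read
#'   data.frames).
#' @export
simulate_fixture <- function(config) {
  assets <- build_toy_genome(config)
  truth <- plan_truth(assets, config)
  reads <- lapply(seq_along(config$conditions), function(i) {
    simulate_sample_reads(assets, truth, config$conditions[i],
                          seed = derive_seed(config$seed, 10L + i),
                          config = config)
  })
  names(reads) <- config$conditions
  list(assets = assets, truth = truth, reads = reads)
}
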
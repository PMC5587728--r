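#' Pipeline orchestration
#'
#' [run_pipeline] chains the full analysis — PASS-read calling, PAS atlas
#' construction, RPM quantification and regulation calls, APA
#' significance/trend statistics and motif analyses — from a validated
#' file-based configuration to a directory of TSV/BED outputs plus a
#' machine-readable JSON summary. Runs are deterministic for fixed
#' inputs and seed.
#'
#' @name workflow
NULL

pipeline_defaults <- function() {
  list(window = 24L, min_reads = 2L, min_frac = 0.05, extension = 4000L,
       fc_cutoff = 2, min_total = 50, fdr = 0.05, pseudocount = 1,
       scan_upstream = 100L, scan_downstream = 100L,
       percentile_cut = "90th", equalize_depth = TRUE, seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, checks parameter ranges and verifies that
#' all referenced paths exist. All problems are reported together.
#'
#' @param config list with `genome` (FASTA path), `annotation` (TSV
#'   path), `samples` (data.frame with `sample_id`, `path`, `condition`),
#'   `pfm` (TSV path, optional: defaults to the bundled synthetic
#'   matrix), `ctrl`/`kd` (condition labels; default the first two
#'   conditions), `out_dir`, and any of the defaults returned by
#'   `apatlas:::pipeline_defaults()`.
#' @return the normalized config (class `run_config`).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  defs <- pipeline_defaults()
  extra <- setdiff(names(config),
                   c(names(defs), "genome", "annotation", "samples", "pfm",
                     "ctrl", "kd", "out_dir"))
  need(length(extra) == 0L,
       paste("unknown config keys:", paste(extra, collapse = ", ")))
  for (k in names(defs)) if (is.null(config[[k]])) config[[k]] <- defs[[k]]

  for (k in c("genome", "annotation")) {
    need(!is.null(config[[k]]), paste(k, "path is required"))
    if (!is.null(config[[k]])) {
      need(file.exists(config[[k]]), paste0(k, " path does not exist: ",
                                            config[[k]]))
    }
  }
  if (is.null(config$pfm)) {
    config$pfm <- system.file("extdata", "starpap_like_pfm_synthetic.tsv",
                              package = "apatlas", mustWork = TRUE)
  } else {
    need(file.exists(config$pfm),
         paste("pfm path does not exist:", config$pfm))
  }
  s <- config$samples
  need(is.data.frame(s) && all(c("sample_id", "path", "condition") %in%
                                 names(s)) && nrow(s) >= 2L,
       "samples must be a data.frame(sample_id, path, condition) with >= 2 rows")
  if (is.data.frame(s) && "path" %in% names(s)) {
    missing <- s$path[!file.exists(s$path)]
    need(length(missing) == 0L,
         paste("sample file(s) missing:", paste(missing, collapse = ", ")))
  }
  if (is.null(config$ctrl) && is.data.frame(s)) {
    config$ctrl <- s$condition[1L]
  }
  if (is.null(config$kd) && is.data.frame(s)) {
    config$kd <- setdiff(s$condition, config$ctrl)[1L]
  }
  need(!is.null(config$out_dir), "out_dir is required")

  need(config$window >= 0, "window must be >= 0")
  need(config$min_reads >= 0, "min_reads must be >= 0")
  need(config$min_frac >= 0 && config$min_frac <= 1,
       "min_frac must be in [0, 1]")
  need(config$fc_cutoff > 0, "fc_cutoff must be positive")
  need(config$min_total >= 0, "min_total must be >= 0")
  need(config$fdr > 0 && config$fdr <= 1, "fdr must be in (0, 1]")
  need(config$extension >= 0, "extension must be >= 0")
  need(config$pseudocount >= 0, "pseudocount must be >= 0")
  need(is.numeric(config$seed) && length(config$seed) == 1L,
       "seed must be a single number")

  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "contig", "strand", "gene_start", "gene_end",
           "last_exon_start", "last_exon_end", "biotype")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  ann
}

write_tsv <- function(x, path, digits = 6L) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = digits)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full APA analysis pipeline
#'
#' Executes, in order: load inputs, PASS-read identification per sample,
#' PAS atlas construction (clustering, gene/region/signal annotation,
#' support filtering), RPM quantification with regulation calls and
#' stratified comparisons, 3'UTR- and upstream-region APA testing with
#' global trend ratios, and motif analyses around the retained PASs.
#' All stage outputs are written as TSV/BED under `out_dir` together
#' with `summary.json` and an MD5 manifest. A stage failure aborts the
#' run with the stage name in the error.
#'
#' @param config a config list (validated via [validate_config]).
#' @return invisibly, a list with `summary` (also written as JSON) and
#'   `manifest` (file checksums).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- list(parameters = unclass(config)[names(pipeline_defaults())])
  paths <- character(0)
  emit <- function(x, name) paths <<- c(paths, write_tsv(
    x, file.path(out_dir, name)))

  inputs <- stage("load", {
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    list(genome = genome,
         annotation = read_gene_annotation(config$annotation),
         pfm = read_pfm(config$pfm))
  })

  pass <- stage("callpas", {
    per_sample <- lapply(seq_len(nrow(config$samples)), function(i) {
      s <- config$samples[i, ]
      rec <- read_alignments(s$path)
      res <- identify_pass_reads(rec, inputs$genome, s$sample_id)
      res$n_records <- nrow(rec)
      res
    })
    names(per_sample) <- config$samples$sample_id
    per_sample
  })
  events <- do.call(rbind, lapply(pass, `[[`, "events"))
  rej <- do.call(rbind, lapply(names(pass), function(s)
    cbind(sample_id = s, pass[[s]]$rejections)))
  summary$reads <- lapply(pass, function(x) list(
    records = x$n_records, pass = nrow(x$events),
    rejected = as.list(table(x$rejections$reason))))
  rej_summary <- as.data.frame(table(sample_id = rej$sample_id,
                                     reason = rej$reason))
  emit(rej_summary, "rejection_summary.tsv")

  atlas <- stage("atlas", {
    tally <- tally_cleavage_sites(events)
    cl <- cluster_cleavage_sites(tally, window = config$window)
    cl <- annotate_pas_location(cl, inputs$annotation,
                                extension = config$extension)
    cl <- annotate_pas_signal(cl, inputs$genome)
    filtered <- filter_pas_clusters(cl, min_reads = config$min_reads,
                                    min_frac = config$min_frac)
    list(all = cl, retained = filtered, n_sites = nrow(tally))
  })
  summary$atlas <- list(
    sites = atlas$n_sites, clusters = nrow(atlas$all$clusters),
    retained = nrow(atlas$retained$clusters),
    genes = length(unique(stats::na.omit(
      atlas$retained$clusters$gene_id))))
  paths <- c(paths, write_pas_bed(atlas$retained,
                                  file.path(out_dir, "atlas.bed")))
  emit(atlas$retained$clusters, "atlas.tsv")
  emit(atlas$retained$counts, "atlas_counts.tsv")

  conditions <- stats::setNames(config$samples$condition,
                                config$samples$sample_id)
  ctrl_s <- config$samples$sample_id[
    config$samples$condition == config$ctrl][1L]
  kd_s <- config$samples$sample_id[
    config$samples$condition == config$kd][1L]

  quant <- stage("quantify", {
    se <- pas_count_table(atlas$retained, conditions = conditions,
                          samples = config$samples$sample_id)
    fc_pas <- call_regulated_transcripts(
      transcript_fold_change(se, kd_s, ctrl_s, level = "pas"),
      fc_cutoff = config$fc_cutoff, min_total = config$min_total)
    fc_gene <- call_regulated_transcripts(
      transcript_fold_change(se, kd_s, ctrl_s, level = "gene"),
      fc_cutoff = config$fc_cutoff, min_total = config$min_total)
    gene_rpm <- gene_level_expression(compute_rpm(se), "rpm")
    strata <- expression_strata(gene_rpm[fc_gene$unit_id, ctrl_s])
    ks_expr <- stratified_ks(fc_gene$log2fc, strata, c("low", "high"))
    list(se = se, fc_pas = fc_pas, fc_gene = fc_gene, ks_expr = ks_expr)
  })
  dur <- attr(quant$fc_pas, "down_up_ratio")
  summary$regulation <- list(
    transcripts_regulated = sum(quant$fc_pas$call != "unchanged"),
    genes_regulated = sum(quant$fc_gene$call != "unchanged"),
    down_up_ratio = dur$ratio, down_up_infinite = dur$infinite,
    ks_low_vs_high_p = quant$ks_expr$p_value)
  emit(quant$fc_pas, "pas_fold_change.tsv")
  emit(quant$fc_gene, "gene_fold_change.tsv")

  apa <- stage("apa", {
    utr <- test_utr_apa(quant$se, ctrl_s, kd_s,
                        fdr_threshold = config$fdr,
                        pseudocount = config$pseudocount,
                        equalize = config$equalize_depth,
                        seed = config$seed)
    ur <- test_ur_apa(quant$se, ctrl_s, kd_s,
                      fdr_threshold = config$fdr,
                      pseudocount = config$pseudocount,
                      equalize = config$equalize_depth,
                      seed = config$seed)
    list(utr = utr, ur = ur,
         utr_trend = gaap_trend(utr, "shortened", "lengthened"),
         ur_trend = gaap_trend(ur, "activated", "suppressed"))
  })
  summary$apa <- list(
    utr_tested = nrow(apa$utr),
    utr_shortened = apa$utr_trend$n_numerator,
    utr_lengthened = apa$utr_trend$n_denominator,
    utr_trend = apa$utr_trend$trend,
    ur_tested = nrow(apa$ur),
    ur_activated = apa$ur_trend$n_numerator,
    ur_suppressed = apa$ur_trend$n_denominator,
    ur_trend = apa$ur_trend$trend)
  emit(apa$utr, "utr_apa.tsv")
  emit(apa$ur, "ur_apa.tsv")
  trends <- data.frame(
    comparison = c("utr_apa", "ur_apa"),
    n_numerator = c(apa$utr_trend$n_numerator, apa$ur_trend$n_numerator),
    n_denominator = c(apa$utr_trend$n_denominator,
                      apa$ur_trend$n_denominator),
    trend = c(apa$utr_trend$trend, apa$ur_trend$trend),
    defined = c(apa$utr_trend$defined, apa$ur_trend$defined))
  emit(trends, "apa_trends.tsv")

  motif <- stage("motif", {
    cl <- atlas$retained$clusters
    flanks <- pas_flanks(inputs$genome, cl,
                         upstream = config$scan_upstream,
                         downstream = config$scan_downstream)
    up_score <- mean_upstream_score(flanks, inputs$pfm,
                                    upstream = config$scan_upstream)
    profile <- build_meta_profile(flanks, inputs$pfm,
                                  upstream = config$scan_upstream)
    fc <- quant$fc_pas[match(cl$cluster_id, quant$fc_pas$unit_id), ]
    ks <- if (nrow(cl) >= 20L && stats::sd(up_score) > 0) {
      percentile_group_ks(up_score, fc$log2fc,
                          cut = config$percentile_cut)
    } else NULL
    down <- fc$call == "down"
    enr <- if (any(down) && any(!down)) {
      reg <- flank_region(flanks, c(-100L, -41L), config$scan_upstream)
      kmer_enrichment(reg[down], reg[!down])
    } else NULL
    comp <- {
      grp <- factor(ifelse(down, "down", "other"))
      if (nlevels(grp) == 2L) {
        signal_composition_test(cl$signal_class, grp, c("down", "other"))
      } else NULL
    }
    list(up_score = data.frame(cluster_id = cl$cluster_id,
                               upstream_score = up_score),
         profile = profile, ks = ks, enr = enr, comp = comp)
  })
  summary$motif <- list(
    percentile_ks_p = if (is.null(motif$ks)) NA else motif$ks$p_value,
    signal_composition_p = if (is.null(motif$comp)) NA else
      motif$comp$p_value,
    top_kmer = if (is.null(motif$enr)) NA else motif$enr$kmer[1L])
  emit(motif$up_score, "upstream_scores.tsv")
  emit(as.data.frame(motif$profile), "motif_profile.tsv")
  if (!is.null(motif$enr)) emit(motif$enr, "kmer_enrichment.tsv")

  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, sj)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(summary = summary, manifest = manifest))
}
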
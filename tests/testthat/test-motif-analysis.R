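test_that("meta profiles average scans and smoothing preserves structure", {
  cp <- conserved_pfm("GCAUAGC")
  set.seed(3)
  fl <- paste(sample(c("A", "C", "G", "T"), 201, TRUE), collapse = "")
  pr <- build_meta_profile(fl, cp)
  expect_equal(pr$score, unname(scan_pas_region(fl, cp)))
  expect_equal(pr$position, -100:94)
  # constant scores smooth to themselves
  prc <- build_meta_profile(strrep("G", 201), conserved_pfm("GGGGGGG"))
  expect_equal(prc$smoothed, prc$score)
  # smoothing roughly preserves the mean
  expect_lt(abs(mean(pr$smoothed) - mean(pr$score)),
            0.05 * max(mean(pr$score), 1e-9))
  # truncated flanks are dropped with a warning
  expect_warning(build_meta_profile(c(fl, substr(fl, 1, 100)), cp),
                 "truncated")
})

test_that("a planted consensus produces a profile peak at its offset", {
  cp <- conserved_pfm("GCAUAGC")
  set.seed(4)
  fl <- vapply(1:100, function(i) {
    x <- paste(sample(c("A", "C", "G", "T"), 201, TRUE), collapse = "")
    substr(x, 31, 37) <- "GCATAGC"   # start position -70
    x
  }, character(1))
  pr <- build_meta_profile(fl, cp)
  expect_equal(pr$position[which.max(pr$score)], -70)
  expect_lte(abs(pr$position[which.max(pr$smoothed)] - (-70)), 3)
})

test_that("mean upstream score averages exactly the contained windows", {
  up <- uniform_pfm()
  set.seed(5)
  fl <- paste(sample(c("A", "C", "G", "T"), 201, TRUE), collapse = "")
  expect_equal(mean_upstream_score(fl, up), 0)
  cp <- conserved_pfm("AAAAAAA")
  # all-N background isolates the planted poly(A) word; overlapping
  # windows at offset d score 2 * (7 - d), so the region mean is
  # (14 + 2 * 2 * (6+5+4+3+2+1)) / 54 = 98 / 54
  flank <- strrep("N", 201)
  substr(flank, 21, 27) <- "AAAAAAA"   # starts at -80, interior windows
  expect_equal(mean_upstream_score(flank, cp), 98 / 54)
  # identical flanks give identical scalars; general equivalence with a
  # direct windowed mean
  cpx <- conserved_pfm("GCAUAGC")
  fl2 <- c(fl, fl)
  ms <- mean_upstream_score(fl2, cpx)
  expect_equal(ms[1], ms[2])
  direct <- mean(vapply(1:54, function(i)
    score_7mer(substr(fl, i, i + 6), cpx), numeric(1)))
  expect_equal(ms[1], direct)
  expect_error(mean_upstream_score(fl, cpx, region = c(-10L, -6L)),
               "shorter")
  # partial windows extend the start range to every overlapping window
  # that exists in the scan (starts -100..-41 here)
  msp <- mean_upstream_score(fl, cpx, partial = TRUE)
  expect_equal(msp, mean(vapply(1:60, function(i)
    score_7mer(substr(fl, i, i + 6), cpx), numeric(1))))
})

test_that("orientation: minus-strand flanks score like their mirrored construction", {
  cfg <- sim_config(n_genes = 40L, n_reads = 50L, motif_frac = 1,
                    seed = 12L)
  assets <- build_toy_genome(cfg)
  pas <- assets$pas_table
  minus <- pas[pas$strand == "-", ][1, ]
  plus <- pas[pas$strand == "+", ][1, ]
  p <- cfg$pfm
  fl_minus <- pas_flanks(assets$genome, minus)
  # mirror the minus-strand locus into a plus-strand genome copy
  L <- length(assets$genome[[1L]])
  mg <- Biostrings::reverseComplement(assets$genome)
  names(mg) <- names(assets$genome)
  mirrored <- minus
  mirrored$strand <- "+"
  mirrored$position <- L - 1L - minus$position
  expect_equal(pas_flanks(mg, mirrored), fl_minus)
  expect_equal(mean_upstream_score(pas_flanks(mg, mirrored), p),
               mean_upstream_score(fl_minus, p))
  # both strands carry the planted consensus upstream
  for (f in c(fl_minus, pas_flanks(assets$genome, plus))) {
    expect_true(grepl(pfm_consensus(p, "DNA"),
                      flank_region(f, c(-100L, -41L))))
  }
})

test_that("percentile grouping and K-S comparison behave at the boundaries", {
  set.seed(6)
  scores <- runif(100)
  vals <- rnorm(100)
  g <- percentile_group_ks(scores, vals)
  expect_equal(sum(g$group == "high"), 10L)
  # identical values across groups: p = 1
  same <- percentile_group_ks(scores, rep(0.5, 100))
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  # all scores equal: degenerate grouping flagged
  expect_warning(deg <- percentile_group_ks(rep(1, 100), vals), "degenerate")
  expect_true(is.na(deg$p_value))
  # tail mode assigns ties at the 10th percentile to the low group
  tails <- percentile_group_ks(scores, vals, cut = "10th/90th")
  expect_equal(sum(tails$group == "low"), 10L)
  expect_equal(sum(tails$group == "high"), 10L)
  expect_error(percentile_group_ks(scores[1:10], vals[1:10]), "20")
  # a planted shift in the top-decile group is detected
  set.seed(7)
  sc <- c(runif(450), 1 + runif(50))
  v <- c(rnorm(450, 0, 0.4), rnorm(50, -1, 0.4))
  expect_lt(percentile_group_ks(sc, v)$p_value, 0.01)
})

test_that("k-mer enrichment matches the hypergeometric oracle", {
  set.seed(8)
  bg <- vapply(1:10, function(i)
    paste(sample(c("C", "G"), 60, TRUE), collapse = ""), character(1))
  grp <- vapply(1:10, function(i) {
    x <- paste(sample(c("C", "G"), 60, TRUE), collapse = "")
    substr(x, 10, 13) <- "ATAA"
    x
  }, character(1))
  enr <- kmer_enrichment(grp, bg)
  expect_equal(nrow(enr), 256L)     # 4^4 rows
  row <- enr[enr$kmer == "AUAA", ]
  expect_equal(row$group_with, 10L)
  expect_equal(row$background_with, 0L)
  expect_equal(row$p_value, oracle_fisher_p(10, 0, 0, 10))
  expect_equal(row$neg_log10_p, -log10(row$p_value))
  # identical composition: all p = 1
  flat <- kmer_enrichment(bg, bg)
  expect_equal(flat$p_value, rep(1, 256))
  expect_error(kmer_enrichment(character(0), bg), "non-empty")
  expect_true(all(enr$group_with <= enr$group_n))
  expect_true(all(enr$p_value > 0 & enr$p_value <= 1))
})

test_that("planted motifs are recovered through the score top decile", {
  cfg <- sim_config(n_genes = 500L, ur_pas_frac = 0, motif_frac = 0.1,
                    seed = 13L)
  assets <- build_toy_genome(cfg)
  pas <- assets$pas_table
  fl <- pas_flanks(assets$genome, pas)
  sc <- mean_upstream_score(fl, cfg$pfm)
  top <- sc > stats::quantile(sc, 0.9)
  tab <- table(factor(top, c(FALSE, TRUE)),
               factor(pas$motif_planted, c(FALSE, TRUE)))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_lt(p, 1e-3)
})

test_that("signal composition tests distinguish homogeneous and split groups", {
  cls <- factor(rep(c("AAUAAA", "none"), each = 50),
                levels = c("AAUAAA", "variant", "A_rich", "none"))
  grp <- factor(rep(c("a", "b"), each = 50))
  res <- signal_composition_test(cls, grp, c("a", "b"))
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$method, "chisq")
  expect_true(all(abs(rowSums(res$proportions) - 1) < 1e-12))
  # identical distributions: p near 1
  cls2 <- factor(rep(c("AAUAAA", "none"), 50),
                 levels = levels(cls))
  res2 <- signal_composition_test(cls2, grp, c("a", "b"))
  expect_gt(res2$p_value, 0.9)
  # sparse tables fall back to the exact test
  cls3 <- factor(rep(c("AAUAAA", "variant"), c(19, 1)),
                 levels = levels(cls))
  grp3 <- factor(rep(c("a", "b"), 10))
  expect_warning(res3 <- signal_composition_test(cls3, grp3, c("a", "b")),
                 "exact")
  expect_equal(res3$method, "fisher")
})
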
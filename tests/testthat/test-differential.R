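# Size factors, dispersion estimation, NB-GLM LRT, BH adjustment and the
# two differential pipelines.

test_that("size factors are median-of-ratios and match the closed forms", {
  m <- matrix(rpois(200, 50) + 1, 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  # identical columns -> all factors 1
  mm <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(mm) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(mm)), rep(1, 3))
  # doubling one column doubles its factor relative to the others
  m2 <- m; m2[, 2] <- m[, 2] * 2L
  sf <- size_factors(m2)
  sf1 <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), unname(2 * sf1[2] / sf1[1]),
               tolerance = 1e-10)
  # single feature: ratio of counts to their geometric mean
  one <- matrix(c(10, 40), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors(one)), c(10, 40) / sqrt(10 * 40))
  expect_error(size_factors(matrix(0, 2, 2)), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(51)
  m <- matrix(rnbinom(2400, mu = 100, size = 10), 200, 12)
  m <- sweep(m, 2, exp(rnorm(12, 0, 0.3)), function(a, b) round(a * b))
  colnames(m) <- paste0("s", 1:12)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-8)
})

test_that("dispersion estimates recover the truth and vanish for Poisson data", {
  set.seed(52)
  pois <- matrix(rpois(2000 * 24, lambda = 100), 2000, 24)
  colnames(pois) <- paste0("s", 1:24)
  a_pois <- estimate_dispersion(pois, sf = rep(1, 24))
  expect_lt(median(a_pois), 0.05)
  # planted alpha = 0.2 recovered within +/- 50%
  nb <- matrix(rnbinom(2000 * 24, mu = 100, size = 1 / 0.2), 2000, 24)
  colnames(nb) <- paste0("s", 1:24)
  a_nb <- estimate_dispersion(nb, sf = rep(1, 24))
  expect_gt(median(a_nb), 0.1)
  expect_lt(median(a_nb), 0.3)
  # constant counts -> floor
  const <- matrix(5, 3, 24, dimnames = list(NULL, paste0("s", 1:24)))
  expect_equal(unname(estimate_dispersion(const, sf = rep(1, 24))),
               rep(1e-8, 3))
})

test_that("the NB LRT matches a Poisson GLM oracle as dispersion -> 0", {
  set.seed(53)
  cfg <- sim_config(seed = 53)
  design <- make_design(cfg)
  m <- matrix(rpois(50 * 24, lambda = 80), 50, 24,
              dimnames = list(NULL, design$sample))
  sf <- rep(1, 24); names(sf) <- design$sample
  res <- nb_lrt(m, design, ~ size + timepoint, ~ size, sf = sf,
                dispersions = rep(1e-8, 50))
  off <- log(sf)
  for (i in 1:50) {
    ff <- stats::glm(m[i, ] ~ size + timepoint, data = design,
                     family = poisson(), offset = off)
    fr <- stats::glm(m[i, ] ~ size, data = design, family = poisson(),
                     offset = off)
    oracle <- as.numeric(2 * (logLik(ff) - logLik(fr)))
    expect_equal(res$stat[i], oracle, tolerance = 1e-3)
  }
  expect_equal(res$df[1], 4L)
  expect_true(all(res$stat >= 0))
})

test_that("all-equal group means give near-zero statistics and p near 1", {
  cfg <- sim_config(seed = 54)
  design <- make_design(cfg)
  m <- matrix(100L, 5, 24, dimnames = list(NULL, design$sample))
  res <- nb_lrt(m, design, ~ size + timepoint, ~ size,
                sf = setNames(rep(1, 24), design$sample),
                dispersions = rep(0.1, 5))
  expect_true(all(res$stat < 1e-6))
  expect_true(all(res$pvalue > 0.999))
})

test_that("null simulations give uniform p-values and nominal type-I error", {
  cfg <- sim_config(seed = 56, effect_fraction = 0)
  design <- make_design(cfg)
  cm <- make_count_matrix(2000L, design, cfg)
  # at the generating dispersion the LRT is calibrated
  res <- nb_lrt(cm, design, ~ size + timepoint, ~ size,
                dispersions = rep(cfg$nb_dispersion, 2000))
  pv <- res$pvalue[!is.na(res$pvalue)]
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.01)
  # with estimated dispersions the plug-in noise makes the test err on the
  # conservative side; it must never be anti-conservative
  res2 <- nb_lrt(cm, design, ~ size + timepoint, ~ size)
  pv2 <- res2$pvalue[!is.na(res2$pvalue)]
  expect_lt(mean(pv2 < 0.05), 0.06)
})

test_that("BH adjustment equals its definitional oracle and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(56)
  for (rep in 1:10) {
    p <- runif(40)^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    # permutation keeps per-item values
    pi <- sample(40)
    expect_equal(bh_adjust(p[pi]), adj[pi])
  }
  # NAs are excluded from m and stay NA
  p <- c(0.01, NA, 0.04)
  a <- bh_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], p.adjust(p, "BH")[c(1, 3)])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("diff_peaks recovers planted time effects under FDR and LFC control", {
  cfg <- sim_config(seed = 57)
  design <- make_design(cfg)
  cm <- make_count_matrix(1000L, design, cfg)
  truth <- attr(cm, "truth")
  dp <- diff_peaks(cm, design)
  disc <- which(dp$significant)
  expect_gt(length(disc), 0)
  fdp <- sum(!truth$affected[disc]) / max(1, length(disc))
  power <- sum(truth$affected[disc]) / sum(truth$affected)
  expect_lte(fdp, 0.10)
  expect_gt(power, 0.5)
  # an infinite LFC threshold silences everything
  dp_inf <- diff_peaks(cm, design, lfc_min = Inf)
  expect_equal(sum(dp_inf$significant), 0L)
})

test_that("effects below the LFC filter are excluded even when padj is small", {
  cfg <- sim_config(seed = 58, effect_log2fc = 1.0, effect_fraction = 0.2)
  design <- make_design(cfg)
  cm <- make_count_matrix(600L, design, cfg)
  dp <- diff_peaks(cm, design)  # lfc_min = 2 > planted 1
  small_effect <- !is.na(dp$padj) & dp$padj < 0.1 & dp$max_abs_log2fc <= 2
  expect_true(any(small_effect))          # the test did detect them
  expect_false(any(dp$significant[small_effect]))
})

test_that("planted log2 fold changes are recovered with small bias", {
  errs <- c()
  for (s in 1:10) {
    cfg <- sim_config(seed = 100 + s, effect_fraction = 0.2)
    design <- make_design(cfg)
    cm <- make_count_matrix(200L, design, cfg)
    truth <- attr(cm, "truth")
    dp <- diff_peaks(cm, design)
    lfc_cols <- paste0("log2fc_timepoint", levels(design$timepoint)[-1])
    for (i in which(truth$affected)) {
      est <- dp[[paste0("log2fc_timepoint", truth$timepoint[i])]][i]
      if (!is.na(est)) errs <- c(errs, est - truth$log2fc[i])
    }
  }
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("day-90 DE uses small as reference and contrasts compose", {
  cfg <- sim_config(seed = 59, effect_fraction = 0.3)
  design <- make_design(cfg)
  em <- make_expression_matrix(100L, design, cfg)
  truth <- attr(em, "truth")
  dg <- diff_genes_day90(em, design)
  # planted up-regulation in large vs small is recovered at FDR 10%
  planted_up <- truth$feature[truth$affected &
                                truth$log2fc_large_vs_small > 0]
  hits <- dg$feature[dg$significant & dg$log2fc_large_vs_small > 0]
  expect_gt(length(intersect(planted_up, hits)) / length(planted_up), 0.5)
  # estimated signs match the planted direction for significant genes
  sig_aff <- dg$significant & truth$affected
  expect_true(all(sign(dg$log2fc_large_vs_small[sig_aff]) ==
                    sign(truth$log2fc_large_vs_small[sig_aff])))
  # A vs L = (A vs S) - (L vs S) on the log2 scale
  expect_equal(dg$log2fc_average_vs_large,
               dg$log2fc_average_vs_small - dg$log2fc_large_vs_small)
  expect_error(diff_genes_day90(em, design, timepoint = "D999"), "no samples")
})
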
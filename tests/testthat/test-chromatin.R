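test_that("promoter windows are strand-aware and clipped", {
  g <- data.frame(gene = c("p", "m", "edge"), chrom = "chr1",
                  strand = c("+", "-", "+"), tss = c(10000, 10000, 500))
  pr <- make_promoters(g)
  expect_equal(pr$start, c(8000L, 9800L, 0L))
  expect_equal(pr$end, c(10200L, 12000L, 700L))
  g2 <- data.frame(gene = "u", chrom = "chr1", strand = ".", tss = 5000)
  expect_warning(pr2 <- make_promoters(g2), "unknown strand")
  expect_equal(pr2$start, 3000L)
  expect_error(make_promoters(data.frame(gene = "x", chrom = "c",
                                         strand = "+", tss = -5)), ">= 0")
})

test_that("peak-support filter applies the stated thresholds", {
  regions <- data.frame(chrom = "chr1", start = c(100, 500),
                        end = c(200, 600), id = c("r1", "r2"))
  peak_in <- data.frame(chrom = "chr1", start = 150, end = 180)
  peak_out <- data.frame(chrom = "chr1", start = 900, end = 950)
  sets <- list(s1 = peak_in, s2 = peak_in, s3 = peak_in, s4 = peak_out)
  kept75 <- filter_regions_by_peak_support(regions, sets, 0.75)
  expect_identical(kept75$id, "r1")
  kept100 <- filter_regions_by_peak_support(regions, sets, 1.0)
  expect_equal(nrow(kept100), 0L)
  # abutting intervals do not overlap (half-open)
  abut <- list(s1 = data.frame(chrom = "chr1", start = 50, end = 100))
  expect_equal(nrow(filter_regions_by_peak_support(regions, abut, 0.5)),
               0L)
  all_sets <- list(s1 = peak_in, s2 = peak_in)
  expect_identical(filter_regions_by_peak_support(regions, all_sets, 1)$id,
                   "r1")
  expect_error(filter_regions_by_peak_support(regions, list(), 0.5),
               ">= 1")
})

test_that("signal-above-input filter drops mean <= 0", {
  sig <- matrix(c(0.5, 0.5, -0.2, 0.0, 0.0, 0.0), 3, 2, byrow = TRUE,
                dimnames = list(c("pos", "neg", "zero"), c("s1", "s2")))
  kept <- filter_by_signal_above_input(sig)
  expect_identical(rownames(kept), "pos")
  expect_identical(filter_by_signal_above_input(sig["pos", , drop = FALSE]),
                   sig["pos", , drop = FALSE])
  expect_message(empty <- filter_by_signal_above_input(
    sig["neg", , drop = FALSE]), "no region")
  expect_equal(nrow(empty), 0L)
})

test_that("signal binning is balanced, ordered and deterministic", {
  set.seed(41)
  sig <- matrix(rnorm(20), 10, 2,
                dimnames = list(sprintf("r%02d", 1:10), c("s1", "s2")))
  bins <- bin_regions_by_mean_signal(sig, 2)
  expect_equal(as.integer(table(bins)), c(5L, 5L))
  mu <- rowMeans(sig)
  expect_true(all(mu[bins == 2] > median(mu) - 1e-12))
  # bin means strictly increasing
  bins5 <- bin_regions_by_mean_signal(sig, 5)
  expect_true(all(diff(tapply(mu, bins5, mean)) > 0))
  # ties broken by region id
  tied <- matrix(1, 4, 2, dimnames = list(c("b", "a", "d", "c"), NULL))
  bt <- bin_regions_by_mean_signal(tied, 2)
  expect_equal(bt[c("a", "b", "c", "d")], c(a = 1L, b = 1L, c = 2L, d = 2L))
  expect_error(bin_regions_by_mean_signal(sig, 11), "fewer regions")
})

test_that("summed peak widths count the full peak, uncclipped", {
  regions <- data.frame(chrom = "chr1", start = 250, end = 400, id = "r")
  peaks <- data.frame(chrom = "chr1", start = 100, end = 300)
  expect_equal(unname(sum_overlapping_peak_widths(regions, peaks)), 200L)
  none <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(unname(sum_overlapping_peak_widths(regions, none)), 0L)
  two <- data.frame(chrom = "chr1", start = c(200, 390), end = c(300, 440))
  expect_equal(unname(sum_overlapping_peak_widths(regions, two)), 150L)
})

test_that("interval logic agrees with a per-base oracle on toy genomes", {
  set.seed(42)
  for (rep_i in 1:20) {
    r_start <- sample(0:9000, 1)
    r_end <- r_start + sample(1:800, 1)
    p_start <- sample(0:9500, 6)
    p_end <- p_start + sample(1:700, 6)
    regions <- data.frame(chrom = "chr1", start = r_start, end = r_end,
                          id = "r")
    peaks <- data.frame(chrom = "chr1", start = p_start, end = p_end)
    expect_equal(
      nrow(filter_regions_by_peak_support(regions, list(s = peaks), 1)) == 1,
      oracle_overlaps(r_start, r_end, p_start, p_end))
    hit <- vapply(seq_along(p_start), function(i) {
      oracle_overlaps(r_start, r_end, p_start[i], p_end[i])
    }, logical(1))
    expect_equal(unname(sum_overlapping_peak_widths(regions, peaks)),
                 sum((p_end - p_start)[hit]))
  }
})

test_that("locus models: planted slope, null predictor, OLS oracle", {
  set.seed(43)
  n <- 30
  x <- rnorm(n)
  sig <- t(sapply(1:50, function(i) 2 * x + rnorm(n, 0, 0.05)))
  rownames(sig) <- sprintf("r%02d", 1:50)
  colnames(sig) <- sprintf("s%02d", 1:n)
  fit <- fit_locus_models(sig, x)
  expect_lt(max(abs(fit$estimate - 2)), 0.1)
  expect_true(all(fit$t > 20))
  # null predictor against independent signals: t centred at 0
  sig0 <- matrix(rnorm(200 * n), 200, n,
                 dimnames = list(sprintf("n%03d", 1:200), colnames(sig)))
  fit0 <- fit_locus_models(sig0, x)
  expect_lt(abs(mean(fit0$t)), 0.25)
  # 6-sample toy against the raw normal-equations oracle
  x6 <- c(0.2, -1.1, 0.5, 1.7, -0.3, 0.9)
  y6 <- rbind(a = c(1, 2, 0, 4, 2, 3), b = c(-2, 1, 0.5, -1, 2, 0))
  colnames(y6) <- sprintf("s%d", 1:6)
  f6 <- fit_locus_models(y6, x6)
  X <- cbind(1, x6)
  expect_equal(f6$t[1], oracle_ols_t(X, y6["a", ]), tolerance = 1e-8)
  expect_equal(f6$t[2], oracle_ols_t(X, y6["b", ]), tolerance = 1e-8)
})

test_that("locus models: cohort effects, interactions, small cohorts", {
  set.seed(44)
  n <- 24
  cohort <- rep(c("a", "b", "tiny"), c(11, 11, 2))
  x <- rnorm(n)
  shift <- c(a = 0, b = 3, tiny = 10)[cohort]
  sig <- t(sapply(1:10, function(i) -1 * x + shift + rnorm(n, 0, 0.1)))
  rownames(sig) <- sprintf("r%d", 1:10)
  colnames(sig) <- sprintf("s%d", 1:n)
  fit <- fit_locus_models(sig, x, cohort = cohort)
  expect_lt(max(abs(fit$estimate + 1)), 0.2)
  # every cohort too small: refuse to fit
  expect_error(fit_locus_models(sig, x, cohort = rep(letters[1:12], 2)),
               ">= 3")
  fit_int <- fit_locus_models(sig, x, cohort = cohort, interaction = TRUE)
  expect_equal(nrow(fit_int), 10L)
  expect_true(all(is.finite(fit_int$t)))
})

test_that("locus models with donors: LMM path and trivial reduction", {
  set.seed(45)
  donors <- rep(sprintf("d%d", 1:6), each = 4)
  n <- length(donors)
  x <- rnorm(n)
  d_eff <- rnorm(6, 0, 2)[as.integer(factor(donors))]
  sig <- t(sapply(1:4, function(i) 1.5 * x + d_eff + rnorm(n, 0, 0.3)))
  rownames(sig) <- sprintf("r%d", 1:4)
  colnames(sig) <- sprintf("s%d", 1:n)
  fit <- fit_locus_models(sig, x, donor = donors)
  expect_true(all(is.finite(fit$t)))
  expect_lt(max(abs(fit$estimate - 1.5)), 0.3)
  # unique donors: silently identical to OLS
  fit_triv <- fit_locus_models(sig, x, donor = sprintf("u%d", 1:n))
  fit_ols <- fit_locus_models(sig, x)
  expect_equal(fit_triv, fit_ols)
})

test_that("null t-values: forced genes, independence, pool guard", {
  set.seed(46)
  n <- 20
  expr <- toy_expr(40, n, seed = 46)
  sig <- matrix(rnorm(100 * n), 100, n,
                dimnames = list(sprintf("r%03d", 1:100), colnames(expr)))
  # degenerate: a single forced gene reproduces the observed fit
  obs <- fit_locus_models(sig, expr["g07", ])
  nul1 <- null_tvalues(sig, expr, genes = "g07")
  expect_equal(unname(nul1), obs$t, tolerance = 1e-12)
  # independent signal: mean null t near 0
  nul <- null_tvalues(sig, expr, n_random = 15, seed = 2)
  expect_lt(abs(mean(nul)), 0.2)
  # different seeds draw different genes but remain finite
  nul_b <- null_tvalues(sig, expr, n_random = 15, seed = 3)
  expect_false(identical(nul, nul_b))
  expect_error(null_tvalues(sig, expr, n_random = 40, seed = 1),
               "not larger")
  expect_error(null_tvalues(sig, expr, n_random = 30,
                            exclusions = rownames(expr)[1:20], seed = 1),
               "not larger")
})

test_that("compare_to_null: exactness, antisymmetry and degeneracy", {
  obs <- c(1, 2, 3, 4, 5, 6)
  expect_equal(compare_to_null(obs, obs)$p.value, 1)
  expect_true(compare_to_null(obs, obs)$all_zero)
  # n = 6, all observed below null: exact two-sided p = 2/2^6
  nul <- obs + c(0.3, 0.5, 0.2, 0.9, 0.6, 0.4)
  res <- compare_to_null(obs, nul)
  expect_equal(res$p.value, 0.03125, tolerance = 1e-12)
  expect_equal(res$p.value, oracle_signed_rank_p(obs - nul),
               tolerance = 1e-12)
  # swapping arguments flips the centred statistic, keeps p
  swapped <- compare_to_null(nul, obs)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p.value, res$p.value)
  # a larger untied case against enumeration
  set.seed(47)
  o2 <- rnorm(12)
  n2 <- o2 + rnorm(12, 0.3)
  expect_equal(compare_to_null(o2, n2)$p.value,
               oracle_signed_rank_p(o2 - n2), tolerance = 1e-10)
  expect_error(compare_to_null(1:3, 2:4), ">= 5")
})

test_that("negative binomial GLM: identities, Poisson limit, coverage", {
  set.seed(48)
  y <- rnbinom(200, mu = 30, size = 2)
  fit <- fit_negative_binomial_glm(y, data.frame(row.names = 1:200))
  expect_equal(exp(fit$coefficients$estimate[1]), mean(y),
               tolerance = 1e-6)
  # Poisson-simulated data: coefficients match the Poisson GLM oracle
  x <- rnorm(300)
  mu <- exp(1 + 0.5 * x)
  yp <- rpois(300, mu)
  fitnb <- fit_negative_binomial_glm(yp, data.frame(x = x))
  fitp <- glm(yp ~ x, family = poisson())
  expect_lt(max(abs(fitnb$coefficients$estimate - coef(fitp))), 1e-3)
  expect_error(fit_negative_binomial_glm(c(1.5, 2), data.frame(x = 1:2)),
               "integers")
  expect_error(fit_negative_binomial_glm(rpois(3, 5),
                                         data.frame(x = 1:3)), "p \\+ 3")
})

test_that("negative binomial GLM: CI coverage on simulated data", {
  set.seed(49)
  covered <- matrix(NA, 200, 2)
  for (i in 1:200) {
    x <- rnorm(120)
    mu <- exp(1 + (-0.5) * x)
    y <- rnbinom(120, mu = mu, size = 2)
    fit <- fit_negative_binomial_glm(y, data.frame(x = x))
    est <- fit$coefficients$estimate
    se <- fit$coefficients$se
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
    covered[i, ] <- c(lo[1] <= 1 & 1 <= hi[1],
                      lo[2] <= -0.5 & -0.5 <= hi[2])
  }
  cov <- colMeans(covered)
  expect_true(all(cov > 0.90 & cov < 0.99))
})

test_that("peak-to-TSS distances follow the stated conventions", {
  genes <- data.frame(gene = c("span", "plus", "minus", "nochrom"),
                      chrom = c("chr1", "chr1", "chr1", "chrX"),
                      strand = c("+", "+", "-", "+"),
                      tss = c(1000, 1000, 1000, 1000))
  peaks <- data.frame(chrom = "chr1",
                      start = c(950, 1200), end = c(1050, 1300))
  d <- peak_tss_distance(genes, peaks)
  expect_equal(unname(d["span"]), 0)
  peaks2 <- data.frame(chrom = "chr1", start = 1200, end = 1300)
  d2 <- peak_tss_distance(genes, peaks2)
  expect_equal(unname(d2["plus"]), 200)
  # minus strand: the same genomic offset is upstream, hence negative
  expect_equal(unname(d2["minus"]), -200)
  expect_true(is.na(d2["nochrom"]))
  expect_error(peak_tss_distance(genes, peaks[0, ]), ">= 1 peak")
  # identical groups give p = 1
  dist <- setNames(c(5, 10, 15, 5, 10, 15), sprintf("g%d", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(peak_distance_group_test(dist, grp)$p.value, 1)
})
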
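test_that("MRN: identical columns give unit size factors", {
  m <- matrix(c(5, 10, 80, 5, 10, 80), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  norm <- mrn_normalize(m)
  expect_equal(unname(norm$size_factors), c(1, 1))
  expect_equal(norm$pseudocounts, m)
})

test_that("MRN matches the hand-computed median-of-ratios example", {
  m <- matrix(c(10, 100, 20, 200), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- mrn_normalize(m)
  expect_equal(unname(norm$size_factors), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-6)
  expect_equal(unname(norm$pseudocounts[, 1]), unname(norm$pseudocounts[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(norm$pseudocounts[, 1]),
               c(10 / sqrt(0.5), 100 / sqrt(0.5)), tolerance = 1e-6)
})

test_that("MRN: zero-count genes appear in output but not size factors", {
  m <- matrix(c(10, 0, 100, 20, 5, 200), 3,
              dimnames = list(c("g1", "gz", "g2"), c("s1", "s2")))
  norm <- mrn_normalize(m)
  ref <- mrn_normalize(m[c("g1", "g2"), ])
  expect_equal(norm$size_factors, ref$size_factors)
  expect_equal(nrow(norm$pseudocounts), 3L)
  m_all_zero_free_missing <- matrix(c(0, 1, 1, 0), 2)
  expect_error(mrn_normalize(m_all_zero_free_missing), "all-positive")
})

test_that("MRN: scaling a sample scales its size factor, not its output", {
  set.seed(1)
  m <- matrix(rpois(200, 50) + 1, 20)
  rownames(m) <- sprintf("g%d", 1:20); colnames(m) <- sprintf("s%d", 1:10)
  norm <- mrn_normalize(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  norm2 <- mrn_normalize(m2)
  # the per-gene geometric means absorb a factor 4^(1/n_samples), so the
  # scaled sample's size factor grows by 4^(1 - 1/n) and every other
  # sample's shrinks by 4^(1/n); pseudocounts change only by the global
  # reference shift, exactly
  g <- 4^(1 / 10)
  expect_equal(unname(norm2$size_factors[3]),
               unname(4 / g * norm$size_factors[3]), tolerance = 1e-12)
  expect_equal(unname(norm2$size_factors[-3]),
               unname(norm$size_factors[-3] / g), tolerance = 1e-12)
  expect_equal(norm2$pseudocounts, norm$pseudocounts * g,
               tolerance = 1e-12)
})

test_that("MRN size factors agree with the DESeq2 reference", {
  set.seed(7)
  m <- matrix(rnbinom(50 * 8, mu = 100, size = 2) + 1, 50, 8)
  rownames(m) <- sprintf("g%02d", 1:50)
  colnames(m) <- sprintf("s%d", 1:8)
  sf <- mrn_normalize(m)$size_factors
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(row.names = colnames(m), x = factor(rep(1:2, 4))), ~1))
  dds <- DESeq2::estimateSizeFactors(dds)
  expect_equal(unname(sf), unname(DESeq2::sizeFactors(dds)),
               tolerance = 1e-8)
  expect_equal(unname(mrn_normalize(m)$pseudocounts),
               unname(DESeq2::counts(dds, normalized = TRUE)),
               tolerance = 1e-8)
})

test_that("gold-standard filter uses a strict threshold", {
  tpm <- matrix(c(6, 6, 6, 4, 0, 9), 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_identical(filter_gold_standard(tpm, 5)$members, "g1")
  # boundary: exactly the threshold is excluded
  tpm2 <- matrix(c(6, 5), 1, dimnames = list("g", c("s1", "s2")))
  expect_error(filter_gold_standard(tpm2, 5), "no gene")
  # threshold 0 with all-positive input keeps everything
  expect_identical(filter_gold_standard(tpm + 1, 0)$members,
                   c("g1", "g2", "g3"))
  expect_error(filter_gold_standard(tpm, -1), "threshold")
})

test_that("group Z-scores: worked example and degenerate groups", {
  m <- matrix(c(1, 2, 3, 7, 7, 7), 2, byrow = TRUE,
              dimnames = list(c("g1", "gconst"), c("s1", "s2", "s3")))
  z <- zscore_by_group(m, rep("a", 3))
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_true(all(is.na(z["gconst", ])))
})

test_that("group Z-scores normalize within each group", {
  set.seed(2)
  m <- matrix(rnorm(5 * 12, 10), 5, 12,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:12)))
  grp <- rep(c("a", "b"), each = 6)
  z <- zscore_by_group(m, grp)
  for (g in c("a", "b")) {
    sub <- z[, grp == g]
    expect_equal(unname(rowMeans(sub)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 1, sd)), rep(1, 5), tolerance = 1e-12)
  }
  # log10 path drops features containing non-positive values
  m[2, 1] <- 0
  expect_warning(z2 <- zscore_by_group(m, grp, log10_first = TRUE),
                 "excluded")
  expect_false("g2" %in% rownames(z2))
  expect_error(zscore_by_group(m, rep(c("a", "b", "c", "d", "e", "f"), 2)),
               ">= 3")
})

test_that("rank percentiles: ties, range and monotone invariance", {
  m <- matrix(c(10, 20, 30, 5, 5, 9), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  p <- rank_percentile_by_group(m, rep("a", 3))
  expect_equal(unname(p["g1", ]), c(1, 2, 3) / 3)
  expect_equal(unname(p["g2", ]), c(0.5, 0.5, 1))
  expect_equal(rank_percentile_by_group(exp(m), rep("a", 3)), p)
  # two groups are ranked independently
  grp <- c("a", "a", "b")
  p2 <- rank_percentile_by_group(m, grp)
  expect_equal(unname(p2["g1", ]), c(0.5, 1, 1))
})

test_that("residualize matches least squares and its properties", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  m <- rbind(g1 = y)
  colnames(m) <- sprintf("s%d", 1:n)
  d <- data.frame(x = x)
  r <- residualize(m, d, fixed = "x")
  expect_lt(abs(cor(r["g1", ], x)), 1e-10)
  expect_equal(unname(r["g1", ]), unname(residuals(lm(y ~ x))),
               tolerance = 1e-8)
  # covariate orthogonal to y leaves centred y
  y0 <- rep(c(1, 3, 5, 7), n / 4)
  x0 <- unname(residuals(lm(rnorm(n) ~ y0)))  # orthogonal by construction
  m0 <- rbind(g = y0)
  colnames(m0) <- sprintf("s%d", 1:n)
  r0 <- residualize(m0, data.frame(x = x0), fixed = "x")
  expect_equal(unname(r0["g", ]), y0 - mean(y0), tolerance = 1e-10)
  # aliased covariates are reported
  d2 <- data.frame(x = x, x2 = 2 * x)
  expect_error(residualize(m, d2, fixed = c("x", "x2")), "aliased")
})

test_that("residualize removes donor variance via the random intercept", {
  set.seed(4)
  n_donor <- 50
  k <- 4
  donor <- rep(sprintf("d%02d", 1:n_donor), each = k)
  reduction <- replicate(20, {
    eff <- rnorm(n_donor, 0, 2)
    y <- eff[as.integer(factor(donor))] + rnorm(n_donor * k, 0, 1)
    m <- rbind(g = y)
    colnames(m) <- sprintf("s%03d", seq_along(y))
    d <- data.frame(donor = donor)
    r_lmm <- residualize(m, d, random_intercept = "donor")
    between <- function(v) var(tapply(v, donor, mean))
    between(r_lmm["g", ]) / between(y - mean(y))
  })
  expect_lt(median(reduction), 0.2)
  # trivial donor grouping reduces to OLS residuals
  m1 <- rbind(g = rnorm(10))
  colnames(m1) <- sprintf("s%d", 1:10)
  d1 <- data.frame(donor = sprintf("d%d", 1:10))
  expect_equal(residualize(m1, d1, random_intercept = "donor")["g", ],
               m1["g", ] - mean(m1["g", ]), tolerance = 1e-10)
})

test_that("residualize supports spline covariates", {
  set.seed(5)
  age <- runif(60, 0, 10)
  y <- sin(age) + rnorm(60, 0, 0.1)
  m <- rbind(g = y)
  colnames(m) <- sprintf("s%d", 1:60)
  r <- residualize(m, data.frame(age = age),
                   spline_covariate = list(name = "age", df = 6))
  expect_lt(sd(r["g", ]), 0.5 * sd(y))
})

test_that("pool_gene_set sums member rows and validates membership", {
  m <- toy_expr(6, 8)
  s <- gene_set("pair", c("g01", "g02"))
  expect_equal(pool_gene_set(m, s), m["g01", ] + m["g02", ])
  expect_equal(pool_gene_set(m, gene_set("one", "g03")), m["g03", ])
  expect_equal(pool_gene_set(m, gene_set("rev", c("g02", "g01"))),
               pool_gene_set(m, s))
  expect_error(pool_gene_set(m, gene_set("bad", c("g01", "nope"))),
               "nope")
  expect_warning(v <- pool_gene_set(m, gene_set("bad", c("g01", "nope")),
                                    missing = "drop"), "nope")
  expect_equal(v, m["g01", ])
})

test_that("cohort admission filter keeps sufficiently large cohorts", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:10),
                     cohort = rep(c("big", "small"), c(7, 3)))
  kept <- filter_cohorts(meta, 5)
  expect_identical(unique(kept$cohort), "big")
  expect_equal(nrow(filter_cohorts(meta, 3)), 10L)
})

test_that("gene_set validates inputs", {
  expect_error(gene_set("x", character()), "empty")
  expect_error(gene_set("x", c("a", "a")), "duplicates")
  gs <- gene_set("x", c("a", "b"), c(a = "H3K4", b = "H3K9"))
  expect_identical(gs$classification[["b"]], "H3K9")
})
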
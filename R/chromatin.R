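# Genomic region construction, peak-support filtering, signal filtering
# and binning, locus-wise models of ChIP signal by expression with
# empirical random-gene nulls, peak widths, NB count regression, and
# peak-to-TSS distances. Coordinates are 0-based half-open (BED native)
# throughout.

#' Promoter windows around TSSs
#'
#' Builds windows from `upstream` bp upstream to `downstream` bp
#' downstream of each TSS, strand-aware and clipped at 0. Unknown strands
#' are treated as "+" with a warning.
#'
#' @param genes data.frame with columns gene, chrom, strand, tss.
#' @param upstream,downstream Window extent in bp (defaults 2000/200).
#' @return data.frame: chrom, start, end, strand, id, class = "promoter".
#' @export
make_promoters <- function(genes, upstream = 2000L, downstream = 200L) {
  if (any(genes$tss < 0)) stop("TSS coordinates must be >= 0")
  strand <- as.character(genes$strand)
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) with unknown strand treated as '+'")
    strand[unknown] <- "+"
  }
  plus <- strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  data.frame(chrom = as.character(genes$chrom),
             start = pmax(0L, as.integer(start)),
             end = as.integer(end), strand = strand,
             id = as.character(genes$gene), class = "promoter",
             stringsAsFactors = FALSE)
}

# Logical: is each region overlapped by >= 1 interval in `peaks`
# (half-open, any shared base)?
regions_overlap_any <- function(regions, peaks) {
  out <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pk)) next
    out[ri] <- vapply(ri, function(i) {
      any(intervals_overlap(regions$start[i], regions$end[i],
                            pk$start, pk$end))
    }, logical(1))
  }
  out
}

#' Filter regions by cross-sample peak support
#'
#' Keeps regions overlapped by at least one peak in at least
#' `min_fraction` of the per-sample peak sets (e.g. 0.75 for broad marks,
#' 1.0 for H3K4me3).
#'
#' @param regions Region data.frame (chrom, start, end, id).
#' @param peak_sets Named list of per-sample BED data.frames.
#' @param min_fraction Minimum supporting fraction of samples.
#' @return The retained subset of `regions`, with a `support` column.
#' @export
filter_regions_by_peak_support <- function(regions, peak_sets,
                                           min_fraction) {
  if (!length(peak_sets)) stop("need >= 1 per-sample peak set")
  hits <- vapply(peak_sets, function(pk) regions_overlap_any(regions, pk),
                 logical(nrow(regions)))
  hits <- matrix(hits, nrow = nrow(regions))
  support <- rowMeans(hits)
  out <- regions[support >= min_fraction, , drop = FALSE]
  out$support <- support[support >= min_fraction]
  out
}

#' Drop regions whose mean signal falls below the input control
#'
#' Removes regions with cross-sample mean log2 fold-change-over-input
#' <= 0.
#'
#' @param signal Signal matrix, regions x samples.
#' @return The retained rows; a message is emitted if nothing survives.
#' @export
filter_by_signal_above_input <- function(signal) {
  keep <- rowMeans(signal) > 0
  if (!any(keep)) message("no region with mean signal above input")
  signal[keep, , drop = FALSE]
}

#' Quantile-bin regions by cross-sample mean signal
#'
#' Equal-count bins (+/-1); ties at bin boundaries are broken by region
#' ID for determinism. Bin 1 holds the lowest signal.
#'
#' @param signal Signal matrix, regions x samples (rownames = region IDs).
#' @param n_bins Number of bins (>= 2).
#' @return Named integer vector of bin labels.
#' @export
bin_regions_by_mean_signal <- function(signal, n_bins) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  L <- nrow(signal)
  if (L < n_bins) stop("fewer regions than bins")
  mu <- rowMeans(signal)
  o <- order(mu, rownames(signal))
  pos <- integer(L)
  pos[o] <- seq_len(L)
  bins <- as.integer(floor((pos - 1) * n_bins / L) + 1)
  setNames(bins, rownames(signal))
}

#' Summed widths of peaks overlapping each region
#'
#' For each region, sums the full width (end - start) of every
#' overlapping peak -- the entire peak, not just the overlapping part.
#' Regions with no overlapping peak get 0.
#'
#' @param regions Region data.frame (chrom, start, end, id).
#' @param peaks BED data.frame of peaks.
#' @return Named numeric vector of summed widths.
#' @export
sum_overlapping_peak_widths <- function(regions, peaks) {
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pk)) next
    w <- as.numeric(pk$end - pk$start)
    out[ri] <- vapply(ri, function(i) {
      hit <- intervals_overlap(regions$start[i], regions$end[i],
                               pk$start, pk$end)
      sum(w[hit])
    }, numeric(1))
  }
  setNames(out, regions$id)
}

# Vectorized OLS of every signal row on a common design matrix; returns
# the slope and t-value of the column named `term` for each locus.
ols_tvalues <- function(X, Y, term) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient design; aliased terms: ",
         paste(colnames(X)[-seq_len(qrx$rank)], collapse = ", "))
  }
  fit <- lm.fit(X, t(Y))
  res <- fit$residuals
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  xtxinv_jj <- chol2inv(qr.R(qrx))[match(term, colnames(X)),
                                   match(term, colnames(X))]
  b <- fit$coefficients[term, ]
  se <- sqrt(sigma2 * xtxinv_jj)
  list(estimate = b, t = b / se, df = dfres)
}

#' Locus-wise models of chromatin signal on expression
#'
#' Fits, for every region, a model explaining signal by the per-sample
#' predictor (an expression residual, protein level or Z-score) with an
#' optional cohort fixed effect, optional predictor-by-cohort
#' interaction, and an optional donor random intercept (REML via lme4).
#' The per-region t-value of the predictor's main effect is the measure
#' of explanatory power. Cohorts with fewer than `min_cohort_size`
#' samples are dropped. When the donor grouping is trivial (one sample
#' per donor) the model silently reduces to ordinary least squares, which
#' is fitted for all loci at once.
#'
#' @param signal Signal matrix, regions x samples.
#' @param predictor Per-sample numeric vector.
#' @param cohort Optional per-sample cohort label (fixed effect).
#' @param interaction Include predictor-by-cohort interaction terms.
#' @param donor Optional per-sample donor ID (random intercept).
#' @param min_cohort_size Cohorts below this are excluded.
#' @return data.frame: region, estimate (slope), t. Loci that cannot be
#'   fitted get NA.
#' @export
fit_locus_models <- function(signal, predictor, cohort = NULL,
                             interaction = FALSE, donor = NULL,
                             min_cohort_size = 3L) {
  n <- ncol(signal)
  if (length(predictor) != n) stop("predictor length must match samples")
  keep <- rep(TRUE, n)
  if (!is.null(cohort)) {
    sizes <- table(cohort)
    keep <- cohort %in% names(sizes)[sizes >= min_cohort_size]
    if (!any(keep)) stop("no cohort with >= ", min_cohort_size, " samples")
    signal <- signal[, keep, drop = FALSE]
    predictor <- predictor[keep]
    cohort <- factor(cohort[keep])
    if (nlevels(cohort) < 2L) cohort <- NULL
  }
  if (!is.null(donor)) {
    donor <- donor[keep]
    if (!anyDuplicated(donor)) donor <- NULL
  }
  d <- data.frame(predictor = predictor)
  rhs <- "predictor"
  if (!is.null(cohort)) {
    d$cohort <- cohort
    rhs <- if (interaction) "predictor * cohort" else "predictor + cohort"
  }
  if (is.null(donor)) {
    X <- model.matrix(as.formula(paste("~", rhs)), d)
    fit <- ols_tvalues(X, signal, "predictor")
    return(data.frame(region = rownames(signal), estimate = fit$estimate,
                      t = fit$t, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  d$donor <- donor
  fml <- as.formula(paste("y ~", rhs, "+ (1 | donor)"))
  est <- tval <- rep(NA_real_, nrow(signal))
  for (i in seq_len(nrow(signal))) {
    d$y <- signal[i, ]
    m <- tryCatch(
      lme4::lmer(fml, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular =
                                               "ignore")),
      error = function(e) NULL)
    if (is.null(m)) next
    co <- summary(m)$coefficients
    est[i] <- co["predictor", "Estimate"]
    tval[i] <- co["predictor", "t value"]
  }
  data.frame(region = rownames(signal), estimate = est, t = tval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical null t-values from random genes
#'
#' Repeats the locus-model fit with the expression of `n_random` genes
#' sampled (under `seed`) from a gold-standard pool, excluding e.g.
#' histone methyltransferases and demethylases, and returns the
#' per-region mean t-value across the random genes.
#'
#' @param signal Signal matrix, regions x samples.
#' @param expr Expression matrix providing candidate predictor rows
#'   (samples aligned with `signal` columns).
#' @param n_random Number of random genes (the published scale is 1,000;
#'   tests use far fewer).
#' @param exclusions [gene_set()] or character vector of genes to
#'   exclude from the pool.
#' @param seed Integer seed for the gene sample.
#' @param genes Optional explicit gene vector, bypassing sampling.
#' @param ... Passed to [fit_locus_models()] (cohort, donor, ...).
#' @return Named numeric vector: per-region mean null t.
#' @export
null_tvalues <- function(signal, expr, n_random = 1000L,
                         exclusions = NULL, seed = 1L, genes = NULL, ...) {
  if (is.null(genes)) {
    pool <- rownames(expr)
    if (!is.null(exclusions)) {
      excl <- if (inherits(exclusions, "gene_set")) exclusions$members
              else as.character(exclusions)
      pool <- setdiff(pool, excl)
    }
    if (length(pool) <= n_random) {
      stop("gold-standard pool (", length(pool),
           ") not larger than n_random (", n_random, ")")
    }
    genes <- with_seed(seed, sample(pool, n_random))
  }
  acc <- matrix(NA_real_, nrow(signal), length(genes))
  for (j in seq_along(genes)) {
    acc[, j] <- fit_locus_models(signal, expr[genes[j], ], ...)$t
  }
  setNames(rowMeans(acc, na.rm = TRUE), rownames(signal))
}

#' Paired comparison of observed vs null t-values
#'
#' Two-sided Wilcoxon signed-rank test of the observed per-region
#' t-values against the per-region mean null t-values. Zero differences
#' are dropped; the p-value is exact for n <= 25 untied differences and
#' uses the normal approximation with continuity correction otherwise.
#' The reported statistic is centred (V - n(n+1)/4), so swapping the
#' arguments flips its sign and keeps the p-value.
#'
#' @param observed,null Aligned per-region numeric vectors.
#' @return list(statistic =, p.value =, n_effective =, all_zero =).
#' @export
compare_to_null <- function(observed, null) {
  if (length(observed) != length(null)) {
    stop("observed and null must be aligned")
  }
  keep <- complete.cases(observed, null)
  if (sum(keep) < 5L) stop("need >= 5 aligned regions")
  d <- observed[keep] - null[keep]
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0L) {
    return(list(statistic = 0, p.value = 1, n_effective = 0L,
                all_zero = TRUE))
  }
  exact <- n_eff <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic) - n_eff * (n_eff + 1) / 4,
       p.value = wt$p.value, n_effective = n_eff, all_zero = FALSE)
}

#' Negative-binomial GLM for overdispersed counts
#'
#' Log-link negative-binomial regression with the dispersion estimated by
#' maximum likelihood (MASS::glm.nb). If the NB fit fails to converge, a
#' Poisson GLM is fitted instead and flagged.
#'
#' @param counts Per-sample non-negative integer response.
#' @param predictors data.frame of per-sample predictors.
#' @return list: `coefficients` (estimate, se, z), `theta` (NB size; NA
#'   for the Poisson fallback), `family`, `converged`.
#' @export
fit_negative_binomial_glm <- function(counts, predictors) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  d <- as.data.frame(predictors)
  if (nrow(d) != length(counts)) stop("predictor rows must match counts")
  if (length(counts) < ncol(d) + 3L) {
    stop("need at least p + 3 samples for p predictors")
  }
  d$.y <- counts
  fml <- as.formula(paste(".y ~", if (ncol(d) > 1L) {
    paste(setdiff(colnames(d), ".y"), collapse = " + ")
  } else "1"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = d)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    co <- summary(fit)$coefficients
    return(list(coefficients = data.frame(term = rownames(co),
                                          estimate = co[, 1L],
                                          se = co[, 2L], z = co[, 3L],
                                          row.names = NULL),
                theta = fit$theta, family = "negative_binomial",
                converged = TRUE))
  }
  pf <- glm(fml, data = d, family = poisson())
  co <- summary(pf)$coefficients
  list(coefficients = data.frame(term = rownames(co), estimate = co[, 1L],
                                 se = co[, 2L], z = co[, 3L],
                                 row.names = NULL),
       theta = NA_real_, family = "poisson", converged = FALSE)
}

#' Signed distances from TSSs to the nearest peak
#'
#' Distance is 0 when a peak spans the TSS; otherwise the gap to the
#' nearest peak boundary, signed negative upstream of the TSS relative
#' to the gene's strand. Genes on chromosomes absent from the peak set
#' get NA.
#'
#' @param genes data.frame with columns gene, chrom, strand, tss.
#' @param peaks BED data.frame of peaks.
#' @return Named numeric vector of signed distances.
#' @export
peak_tss_distance <- function(genes, peaks) {
  if (!nrow(peaks)) stop("need >= 1 peak")
  out <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    pk <- peaks[peaks$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(pk)) next
    tss <- genes$tss[i]
    spans <- pk$start <= tss & tss < pk$end
    if (any(spans)) {
      out[i] <- 0
      next
    }
    d_genomic <- ifelse(pk$start > tss, pk$start - tss, pk$end - tss)
    d <- d_genomic[which.min(abs(d_genomic))]
    out[i] <- if (identical(genes$strand[i], "-")) -d else d
  }
  setNames(out, genes$gene)
}

#' Rank-sum comparison of peak distances between gene groups
#'
#' Two-sided Wilcoxon rank-sum test on (absolute) peak-to-TSS distances
#' between two gene groups.
#'
#' @param distances Named numeric distances from [peak_tss_distance()].
#' @param groups Factor/character with exactly two levels, aligned with
#'   `distances`.
#' @param absolute Compare |distance| (default) rather than signed.
#' @return list(statistic =, p.value =).
#' @export
peak_distance_group_test <- function(distances, groups, absolute = TRUE) {
  keep <- !is.na(distances)
  d <- distances[keep]
  g <- factor(groups[keep])
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (absolute) d <- abs(d)
  wt <- suppressWarnings(
    wilcox.test(d[g == levels(g)[1L]], d[g == levels(g)[2L]],
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}
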
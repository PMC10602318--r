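# Normalization, transforms, filtering, residualization and gene-set
# pooling applied upstream of all correlation analyses.

#' Construct a gene set
#'
#' @param name Set name (e.g. "HMT").
#' @param members Character vector of gene IDs; must be non-empty and
#'   unique.
#' @param classification Optional named character vector mapping members to
#'   a class label (e.g. target residue H3K4/H3K9/H3K27/H3K36/H4K20, or
#'   activation/repression/unclear).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, classification = NULL) {
  members <- as.character(members)
  if (length(members) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(members)) stop("gene set '", name, "' has duplicates")
  if (!is.null(classification)) {
    classification <- classification[members]
  }
  structure(list(name = as.character(name), members = members,
                 classification = classification),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$members)))
  invisible(x)
}

#' Median-ratio normalization (MRN)
#'
#' Per-sample size factors are the median, over genes with no zero count,
#' of the ratio of the sample's count to the gene's geometric mean across
#' samples. Pseudocounts are counts divided by the sample size factor.
#' Genes with a zero count still appear in the output matrix; they simply
#' do not inform size-factor estimation.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return list with `pseudocounts` (matrix) and `size_factors` (named
#'   numeric, one per sample).
#' @export
mrn_normalize <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2L) {
    stop("mrn_normalize needs a matrix with >= 2 samples")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_free <- rowSums(counts == 0) == 0L
  if (!any(zero_free)) {
    stop("no gene with all-positive counts; cannot estimate size factors")
  }
  log_geo <- rowMeans(log(counts[zero_free, , drop = FALSE]))
  log_ratios <- log(counts[zero_free, , drop = FALSE]) - log_geo
  size_factors <- exp(apply(log_ratios, 2, median))
  names(size_factors) <- colnames(counts)
  pseudo <- sweep(counts, 2, size_factors, "/")
  list(pseudocounts = pseudo, size_factors = size_factors)
}

#' Universally expressed ("gold standard") gene filter
#'
#' Keeps genes whose TPM exceeds `threshold` in every sample (strict
#' inequality), mirroring the restriction to ubiquitously expressed genes
#' used to keep Z-score analyses free of zeros.
#'
#' @param tpm TPM matrix, genes x samples.
#' @param threshold Minimum TPM, strict; must be >= 0.
#' @param name Name for the resulting set.
#' @return A [gene_set()] of the retained genes.
#' @export
filter_gold_standard <- function(tpm, threshold = 5, name = "gold_standard") {
  if (threshold < 0) stop_config("threshold", "must be >= 0")
  keep <- rowSums(tpm > threshold) == ncol(tpm)
  if (!any(keep)) stop("no gene passes the TPM threshold")
  gene_set(name, rownames(tpm)[keep])
}

#' Group-wise Z-score transform
#'
#' Centres and scales each feature within each group (sample standard
#' deviation). With `log10_first = TRUE` values are log10-transformed
#' before Z-scoring; features containing non-positive values are then
#' dropped with a warning (restrict to universally expressed genes to
#' avoid this). Features constant within a group become NA for that group
#' rather than +/-Inf.
#'
#' @param values Numeric matrix, features x samples.
#' @param group Per-sample group label (length = ncol).
#' @param log10_first Apply log10 before Z-scoring.
#' @param min_group_size Groups smaller than this raise an error.
#' @return Matrix of Z-scores, same shape (possibly fewer rows when
#'   `log10_first` drops features).
#' @export
zscore_by_group <- function(values, group, log10_first = FALSE,
                            min_group_size = 3L) {
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    stop("group labels must match the number of samples")
  }
  if (any(table(group) < min_group_size)) {
    stop("every group needs >= ", min_group_size, " samples")
  }
  if (log10_first) {
    bad <- rowSums(values <= 0 | !is.finite(values)) > 0
    if (any(bad)) {
      warning(sum(bad), " feature(s) with non-positive values excluded ",
              "before log10")
      values <- values[!bad, , drop = FALSE]
    }
    values <- log10(values)
  }
  out <- values
  for (g in unique(group)) {
    idx <- which(group == g)
    sub <- values[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    z <- (sub - mu) / sdv
    z[sdv == 0, ] <- NA_real_
    out[, idx] <- z
  }
  out
}

#' Group-wise rank-percentile transform
#'
#' Within each group, values are ranked (average ties) and divided by the
#' group size, giving percentiles in (0, 1]. Invariant to strictly
#' monotone transforms of the input.
#'
#' @inheritParams zscore_by_group
#' @return Matrix of rank percentiles.
#' @export
rank_percentile_by_group <- function(values, group) {
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    stop("group labels must match the number of samples")
  }
  if (any(!nzchar(group)) || length(group) == 0L) stop("empty group label")
  out <- values
  for (g in unique(group)) {
    idx <- which(group == g)
    sub <- values[, idx, drop = FALSE]
    out[, idx] <- t(apply(sub, 1, rank)) / length(idx)
  }
  out
}

#' Residualize expression on covariates
#'
#' Per-feature linear (or linear mixed) model residuals. Fixed covariates
#' enter as given; an optional donor column is fitted as a random
#' intercept by REML (lme4); an optional covariate can instead be expanded
#' into a natural cubic spline basis with the stated degrees of freedom
#' (used e.g. for inferred developmental age).
#'
#' When the donor grouping is trivial (every donor contributes one
#' sample), the random intercept is dropped and the fit reduces to
#' ordinary least squares.
#'
#' @param values Numeric matrix, features x samples.
#' @param data data.frame of per-sample covariates (nrow = ncol(values)).
#' @param fixed Character vector of column names in `data` used as fixed
#'   effects; may be empty.
#' @param random_intercept Optional column name in `data` giving the donor
#'   (random intercept) grouping.
#' @param spline_covariate Optional list(name =, df =) naming a numeric
#'   column to expand as splines::ns(x, df).
#' @return Matrix of residuals, same shape as `values`.
#' @export
residualize <- function(values, data, fixed = character(),
                        random_intercept = NULL, spline_covariate = NULL) {
  if (nrow(data) != ncol(values)) {
    stop("covariate table must have one row per sample")
  }
  terms <- fixed
  if (!is.null(spline_covariate)) {
    terms <- c(terms, sprintf("splines::ns(%s, df = %d)",
                              spline_covariate$name,
                              as.integer(spline_covariate$df)))
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  use_lmm <- FALSE
  if (!is.null(random_intercept)) {
    groups <- data[[random_intercept]]
    if (length(unique(groups)) < length(groups)) {
      use_lmm <- TRUE
    }
  }
  X <- model.matrix(as.formula(paste("~", rhs)), data = data)
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[-seq_len(qr(X)$rank)]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  out <- values
  if (!use_lmm) {
    fit <- lm.fit(X, t(values))
    out[] <- t(fit$residuals)
    return(out)
  }
  fml <- as.formula(paste("y ~", rhs, "+ (1 |", random_intercept, ")"))
  for (i in seq_len(nrow(values))) {
    d <- data
    d$y <- values[i, ]
    m <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
    out[i, ] <- residuals(m)
  }
  out
}

#' Pool a gene set into a per-sample total
#'
#' Sums member pseudocounts per sample. Missing members raise an error
#' naming them, unless `missing = "drop"`.
#'
#' @param expr Expression matrix (pseudocounts), genes x samples.
#' @param set A [gene_set()] or character vector of gene IDs.
#' @param missing "error" (default) or "drop" (warn and pool the rest).
#' @return Named numeric vector, one total per sample.
#' @export
pool_gene_set <- function(expr, set, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  absent <- setdiff(members, rownames(expr))
  if (length(absent)) {
    if (missing == "error") {
      stop("gene set members absent from matrix: ",
           paste(absent, collapse = ", "))
    }
    warning("dropping absent members: ", paste(absent, collapse = ", "))
    members <- setdiff(members, absent)
    if (!length(members)) stop("no members left after dropping")
  }
  colSums(expr[members, , drop = FALSE])
}

#' Cohort admission filter
#'
#' Keeps samples whose cohort has at least `min_samples` members, the
#' configurable analogue of requiring >= 100 GTEx / >= 35 TCGA primary
#' tumour / >= 20 CCLE samples per disease type.
#'
#' @param metadata data.frame with a `sample_id` column and the cohort
#'   column named by `cohort_col`.
#' @param min_samples Minimum cohort size.
#' @param cohort_col Name of the cohort column.
#' @return The admitted subset of `metadata`.
#' @export
filter_cohorts <- function(metadata, min_samples, cohort_col = "cohort") {
  sizes <- table(metadata[[cohort_col]])
  keep <- names(sizes)[sizes >= min_samples]
  metadata[metadata[[cohort_col]] %in% keep, , drop = FALSE]
}
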
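# Pooling-trajectory analysis: how the correlation of a target gene with
# the cumulative sum of a gene set evolves as members are pooled in random
# order, plus the co-regulation toy model with its closed-form oracle.

#' Co-regulation simulator configuration
#'
#' A theoretical co-regulator C ~ Normal(0, 1) positively regulates
#' `n_genes` genes (A_i = C + eps_i) and negatively regulates one gene
#' (B = -C + delta). The defaults (40 genes, 500 samples, 1,000
#' repetitions) match the published toy model; the noise SDs are
#' unstated there and default to 1.
#'
#' @param n_genes Number of positively regulated genes.
#' @param n_samples Samples per repetition.
#' @param n_reps Repetitions.
#' @param noise_sd_a Per-A-gene noise SD.
#' @param noise_sd_b B-gene noise SD.
#' @param seed Integer seed.
#' @param new_order_each_rep Draw a fresh pooling order per repetition
#'   (default) or reuse one fixed order.
#' @return list of class `coreg_config`.
#' @export
coreg_config <- function(n_genes = 40L, n_samples = 500L, n_reps = 1000L,
                         noise_sd_a = 1, noise_sd_b = 1, seed = 1L,
                         new_order_each_rep = TRUE) {
  structure(list(
    n_genes = check_count(n_genes, "n_genes"),
    n_samples = check_count(n_samples, "n_samples", 4L),
    n_reps = check_count(n_reps, "n_reps"),
    noise_sd_a = check_scalar_number(noise_sd_a, "noise_sd_a", 0),
    noise_sd_b = check_scalar_number(noise_sd_b, "noise_sd_b", 0),
    seed = check_count(seed, "seed", 0L),
    new_order_each_rep = isTRUE(new_order_each_rep)
  ), class = "coreg_config")
}

#' Expected pooled correlation under the co-regulation model
#'
#' Closed form for the Pearson correlation of B with the sum of k pooled
#' A genes: corr_k = -1 / sqrt((1 + sd_a^2 / k) (1 + sd_b^2)). The
#' magnitude increases strictly in k towards the asymptote
#' 1 / sqrt(1 + sd_b^2).
#'
#' @param k Pool size(s).
#' @param noise_sd_a,noise_sd_b Noise SDs of the model.
#' @return Expected correlation(s), negative.
#' @export
coreg_expected_corr <- function(k, noise_sd_a = 1, noise_sd_b = 1) {
  -1 / sqrt((1 + noise_sd_a^2 / k) * (1 + noise_sd_b^2))
}

new_pooling_trajectory <- function(mat, method, orders = NULL) {
  colnames(mat) <- as.character(seq_len(ncol(mat)))
  structure(list(correlations = mat, method = method, orders = orders),
            class = "pooling_trajectory")
}

#' @export
print.pooling_trajectory <- function(x, ...) {
  cat(sprintf("<pooling_trajectory: %d iterations x pool sizes 1..%d (%s)>\n",
              nrow(x$correlations), ncol(x$correlations), x$method))
  invisible(x)
}

#' Pooling trajectory of a target against a gene set
#'
#' For each of `n_orders` seeded random orderings of the set, the target
#' is correlated with the cumulative per-sample sum of member
#' pseudocounts at every pool size. The final column is order-invariant
#' (the full pool). A loess trend of correlation on pool size is fitted
#' across all iteration points.
#'
#' @param expr Expression matrix (pseudocounts), genes x samples.
#' @param set [gene_set()]; must not contain the target.
#' @param target Gene ID to correlate against.
#' @param n_orders Number of random orderings (>= 1).
#' @param seed Integer seed.
#' @param method Correlation method.
#' @param span Loess span for the trend.
#' @return `pooling_trajectory` with elements `correlations`
#'   (n_orders x pool-size matrix), `orders`, `method`, `trend`
#'   (data.frame pool_size, fit).
#' @export
pooling_trajectory <- function(expr, set, target, n_orders = 100L,
                               seed = 1L, method = c("spearman", "pearson"),
                               span = 0.5) {
  method <- match.arg(method)
  members <- if (inherits(set, "gene_set")) set$members else set
  if (target %in% members) stop("target must not be a member of the set")
  absent <- setdiff(members, rownames(expr))
  if (length(absent)) {
    stop("set members absent: ", paste(absent, collapse = ", "))
  }
  if (n_orders < 1L) stop("n_orders must be >= 1")
  y <- expr[target, ]
  k <- length(members)
  with_seed(seed, {
    orders <- lapply(seq_len(n_orders), function(i) sample(members))
    mat <- matrix(NA_real_, n_orders, k)
    for (i in seq_len(n_orders)) {
      pooled <- apply(expr[orders[[i]], , drop = FALSE], 2, cumsum)
      pooled <- matrix(pooled, nrow = k)  # k x samples even when k == 1
      mat[i, ] <- cor_vec_mat(y, t(pooled), method)$r
    }
    traj <- new_pooling_trajectory(mat, method, orders)
    traj$trend <- fit_trend(mat, span)
    traj
  })
}

fit_trend <- function(mat, span = 0.5) {
  k <- ncol(mat)
  df <- data.frame(pool_size = rep(seq_len(k), each = nrow(mat)),
                   correlation = as.vector(mat))
  # loess needs a reasonable number of distinct pool sizes; fall back to
  # per-size means for short trajectories
  fit <- if (k >= 10L) {
    lo <- loess(correlation ~ pool_size, data = df, span = span,
                degree = 2)
    predict(lo, newdata = data.frame(pool_size = seq_len(k)))
  } else {
    tapply(df$correlation, df$pool_size, mean)
  }
  data.frame(pool_size = seq_len(k), fit = as.numeric(fit))
}

#' Simulate the co-regulation toy model
#'
#' Per repetition: draw the co-regulator per sample, A_i = C + eps_i,
#' B = -C + delta, then correlate B against the cumulative sum of A genes
#' pooled in (by default, a fresh) random order.
#'
#' @param config A [coreg_config()].
#' @return `pooling_trajectory` (n_reps x n_genes correlation matrix).
#' @export
simulate_coregulation <- function(config) {
  if (!inherits(config, "coreg_config")) {
    stop("config must be created by coreg_config()")
  }
  with_seed(config$seed, {
    k <- config$n_genes
    n <- config$n_samples
    mat <- matrix(NA_real_, config$n_reps, k)
    for (rep_i in seq_len(config$n_reps)) {
      C <- rnorm(n)
      A <- C + matrix(rnorm(n * k, 0, config$noise_sd_a), n, k)
      B <- -C + rnorm(n, 0, config$noise_sd_b)
      if (config$new_order_each_rep || rep_i == 1L) {
        ord <- sample.int(k)
      }
      pooled <- apply(A[, ord, drop = FALSE], 1, cumsum)  # k x n
      pooled <- matrix(pooled, nrow = k)
      mat[rep_i, ] <- cor_vec_mat(B, t(pooled), "pearson")$r
    }
    traj <- new_pooling_trajectory(mat, "pearson")
    traj$trend <- fit_trend(mat)
    traj
  })
}

#' Summarise a pooling trajectory
#'
#' Per-pool-size quantiles of the correlations and a monotonicity
#' statistic: the Spearman correlation of the median |correlation| with
#' pool size (1 = strictly strengthening). A constant trajectory has
#' undefined monotonicity, reported as 0 with `degenerate = TRUE`.
#'
#' @param traj A `pooling_trajectory`.
#' @return list: `by_size` (data.frame pool_size, median, q25, q75),
#'   `monotonicity`, `degenerate`.
#' @export
trajectory_summary <- function(traj) {
  mat <- traj$correlations
  if (!nrow(mat)) stop("empty trajectory")
  by_size <- data.frame(
    pool_size = seq_len(ncol(mat)),
    median = apply(mat, 2, median),
    q25 = apply(mat, 2, quantile, 0.25),
    q75 = apply(mat, 2, quantile, 0.75)
  )
  med_abs <- abs(by_size$median)
  degenerate <- length(unique(med_abs)) == 1L || ncol(mat) < 2L
  mono <- if (degenerate) 0 else {
    cor(med_abs, by_size$pool_size, method = "spearman")
  }
  list(by_size = by_size, monotonicity = mono, degenerate = degenerate)
}
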
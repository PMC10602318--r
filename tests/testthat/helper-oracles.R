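# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (formula-level, enumeration, per-base) so they share
# no code path with the package implementations they check.

# Product-moment correlation straight from the defining formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Two-sided p from the t transformation of r.
oracle_cor_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t), n - 2, lower.tail = FALSE)
}

# BH step-up by the textbook definition: q_(i) = min over j >= i of
# m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns on the ranks of |d| (requires untied, non-zero d).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Two-sided Fisher p by full hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more probable than the
# observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Per-base interval overlap on a toy genome: materialise covered bases
# (0-based, half-open) and intersect.
oracle_bases <- function(start, end) {
  unlist(mapply(function(s, e) if (e > s) seq(s, e - 1L) else integer(),
                start, end, SIMPLIFY = FALSE))
}

oracle_overlaps <- function(r_start, r_end, p_start, p_end) {
  rb <- seq(r_start, r_end - 1L)
  any(vapply(seq_along(p_start), function(i) {
    length(intersect(rb, oracle_bases(p_start[i], p_end[i]))) > 0
  }, logical(1)))
}

# OLS slope t-value from the raw normal equations.
oracle_ols_t <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  (beta / se)[2L]
}

# Small deterministic toy expression matrix.
toy_expr <- function(n_genes = 20, n_samples = 30, seed = 42) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, 3, 1), n_genes, n_samples)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}
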
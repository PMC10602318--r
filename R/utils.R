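# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All stochastic operations in the package funnel through this so that a
# user-supplied seed gives bit-identical output regardless of surrounding
# RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a sub-stream seed from a base seed by a fixed offset, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% .Machine$integer.max)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_config(field, sprintf("must be > %s", lower))
  }
  if (!strict_lower && x < lower) {
    stop_config(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_config(field, sprintf("must be <= %s", upper))
  invisible(x)
}

check_count <- function(x, field, minimum = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x != as.integer(x) || x < minimum) {
    stop_config(field, sprintf("must be an integer >= %d", minimum))
  }
  invisible(as.integer(x))
}

# Column-wise Pearson correlation of a vector against every column of a
# matrix, with two-sided p-values from the t transformation. Constant
# columns yield NA. Used by several modules, so kept fast and allocation
# light.
cor_vec_mat <- function(x, m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (method == "spearman") {
    x <- rank(x)
    m <- apply(m, 2, rank)
  }
  n <- length(x)
  xc <- x - mean(x)
  mc <- sweep(m, 2, colMeans(m))
  sx <- sqrt(sum(xc^2))
  sm <- sqrt(colSums(mc^2))
  r <- as.vector(crossprod(mc, xc)) / (sx * sm)
  r[sm == 0 | sx == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}

# Half-open interval overlap: [s1, e1) intersects [s2, e2).
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}
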
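# Correlation machinery: single-cohort and rank-sampled cross-cohort
# correlations, FDR control, partial correlation, metabolite-gene
# association, and co-expression networks.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, capped at 1 and monotone non-decreasing in p-order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same order as input.
#' @export
fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0L) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  q
}

#' Correlate one feature against every gene
#'
#' Per-gene Pearson or Spearman correlation of a per-sample feature vector
#' (a gene's expression, a pooled gene-set total, a metabolite) against
#' all rows of an expression matrix, with two-sided p-values from the t
#' transformation, BH q-values, and an anticorrelation rank (1 = most
#' negative correlation; ties broken by gene ID).
#'
#' @param feature Per-sample numeric vector (length = ncol(expr)).
#' @param expr Expression matrix, genes x samples.
#' @param method "pearson" or "spearman".
#' @return data.frame of class `correlation_result`: gene, r, p, q,
#'   anticorr_rank, plus attributes `method` and `n`.
#' @export
correlate_feature_vs_genes <- function(feature, expr,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(feature) != ncol(expr)) {
    stop("feature length must equal the number of samples")
  }
  if (length(unique(feature)) == 1L) stop("feature is constant")
  cc <- cor_vec_mat(feature, t(expr), method)
  res <- data.frame(gene = rownames(expr), r = cc$r, p = cc$p,
                    q = fdr_bh(cc$p), stringsAsFactors = FALSE)
  res$anticorr_rank <- anticorrelation_rank(res$r, res$gene)
  attr(res, "method") <- method
  attr(res, "n") <- cc$n
  class(res) <- c("correlation_result", "data.frame")
  res
}

# Rank genes by ascending correlation; ties broken lexicographically by
# gene ID so ranks are a deterministic permutation of 1..N. NAs sink to
# the end.
anticorrelation_rank <- function(r, ids) {
  o <- order(r, ids, na.last = TRUE)
  rk <- integer(length(r))
  rk[o] <- seq_along(r)
  rk
}

#' Rank-sampled cross-cohort Spearman correlation
#'
#' To combine cohorts without letting high-expressing cohorts dominate,
#' each iteration samples `n_per_cohort` samples per cohort (without
#' replacement by default), ranks every gene within the sampled subset of
#' each cohort, concatenates the ranks across cohorts, and computes the
#' Spearman correlation of every gene's concatenated ranks against the
#' target's. The per-gene median over `n_iter` iterations is returned.
#'
#' Cohorts with fewer than `n_per_cohort` samples contribute all their
#' samples (default) or are sampled with replacement when
#' `replace = TRUE`.
#'
#' @param expr Expression matrix (pseudocounts), genes x samples.
#' @param cohort Per-sample cohort label.
#' @param target Per-sample numeric vector (gene row or pooled set total).
#' @param n_per_cohort Samples drawn per cohort per iteration.
#' @param n_iter Number of sampling iterations.
#' @param seed Integer seed.
#' @param replace Sample with replacement when a cohort is short.
#' @return Named numeric vector: per-gene median Spearman rho.
#' @export
pan_cohort_correlation <- function(expr, cohort, target, n_per_cohort,
                                   n_iter = 100L, seed = 1L,
                                   replace = FALSE) {
  cohort <- as.character(cohort)
  if (length(cohort) != ncol(expr)) {
    stop("cohort labels must match the number of samples")
  }
  idx_by_cohort <- split(seq_along(cohort), cohort)
  if (!length(idx_by_cohort)) stop("no admitted cohorts")
  with_seed(seed, {
    rho <- matrix(NA_real_, nrow(expr), n_iter)
    for (it in seq_len(n_iter)) {
      chunks_t <- list(); chunks_e <- list()
      for (ci in seq_along(idx_by_cohort)) {
        idx <- idx_by_cohort[[ci]]
        take <- if (length(idx) >= n_per_cohort) {
          sample(idx, n_per_cohort)
        } else if (replace) {
          sample(idx, n_per_cohort, replace = TRUE)
        } else {
          idx
        }
        sub <- expr[, take, drop = FALSE]
        chunks_e[[ci]] <- t(apply(sub, 1, rank))
        chunks_t[[ci]] <- rank(target[take])
      }
      tvec <- unlist(chunks_t, use.names = FALSE)
      emat <- do.call(cbind, chunks_e)
      rho[, it] <- cor_vec_mat(tvec, t(emat), "spearman")$r
    }
    setNames(apply(rho, 1, median), rownames(expr))
  })
}

#' Metabolite-gene correlations on group-wise Z-scores
#'
#' Both metabolite abundances and gene expression are Z-scored within
#' each group (disease type); expression is log10-transformed first. The
#' Z-scores are pooled across groups and each (metabolite, gene) pair is
#' correlated (Pearson), with BH-FDR per metabolite across genes. When
#' gene sets are supplied, the per-metabolite summary is the geometric
#' mean of the members' FDR.
#'
#' @param metab Metabolite matrix, metabolites x samples.
#' @param expr Expression matrix (pseudocounts), genes x samples; should
#'   be restricted to universally expressed genes.
#' @param group Per-sample group label (shared samples only are used).
#' @param gene_sets Optional list of [gene_set()] objects to summarise.
#' @return list: `pairs` (data.frame metabolite, gene, r, p, q) and
#'   `set_summary` (data.frame metabolite, set, geometric_mean_fdr), NULL
#'   when no sets given.
#' @export
metabolite_gene_correlations <- function(metab, expr, group,
                                         gene_sets = NULL) {
  shared <- intersect(colnames(metab), colnames(expr))
  if (!length(shared)) stop("no shared samples between matrices")
  names(group) <- names(group) %||% colnames(expr)
  metab <- metab[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  grp <- group[shared]
  mz <- zscore_by_group(metab, grp)
  ez <- zscore_by_group(expr, grp, log10_first = TRUE)
  out <- vector("list", nrow(mz))
  for (i in seq_len(nrow(mz))) {
    cc <- cor_vec_mat(mz[i, ], t(ez), "pearson")
    out[[i]] <- data.frame(metabolite = rownames(mz)[i],
                           gene = rownames(ez), r = cc$r, p = cc$p,
                           q = fdr_bh(cc$p), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  set_summary <- NULL
  if (!is.null(gene_sets)) {
    rows <- list()
    for (s in gene_sets) {
      for (m in rownames(mz)) {
        sub <- pairs[pairs$metabolite == m & pairs$gene %in% s$members, ]
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, set = s$name,
          geometric_mean_fdr = geometric_mean(sub$q),
          stringsAsFactors = FALSE)
      }
    }
    set_summary <- do.call(rbind, rows)
  }
  list(pairs = pairs, set_summary = set_summary)
}

geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  exp(mean(log(x)))
}

#' First-order partial correlation
#'
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' equivalently the correlation of the OLS residuals of x|z and y|z.
#'
#' @param x,y,z Per-sample numeric vectors.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  keep <- complete.cases(x, y, z)
  if (sum(keep) < 5L) stop("need >= 5 complete triples")
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("control variable is degenerate (|r| = 1 with x or y)")
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Build a co-expression network
#'
#' Pairwise Spearman correlations among gene-set members on
#' confounder-corrected, rank-percentile-transformed expression; edges
#' are kept when |rho| >= threshold. Members with constant expression are
#' excluded with a warning.
#'
#' @param expr Expression matrix, genes x samples.
#' @param set [gene_set()] with >= 2 members present in the matrix.
#' @param threshold Minimum |rho| for an edge.
#' @param method Correlation method.
#' @return list of class `coexpression_network`: nodes, edges (data.frame
#'   a, b, weight), threshold, degree (named integer).
#' @export
build_coexpression_network <- function(expr, set, threshold = 0.2,
                                       method = "spearman") {
  members <- intersect(set$members, rownames(expr))
  if (length(members) < 2L) stop("need >= 2 set members in the matrix")
  sub <- expr[members, , drop = FALSE]
  const <- apply(sub, 1, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("excluding constant members: ",
            paste(members[const], collapse = ", "))
    members <- members[!const]
    sub <- sub[members, , drop = FALSE]
  }
  cm <- cor(t(sub), method = method)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[idx]
  keep <- !is.na(w) & abs(w) >= threshold
  edges <- data.frame(a = members[idx[keep, 1L]],
                      b = members[idx[keep, 2L]],
                      weight = w[keep], stringsAsFactors = FALSE)
  degree <- setNames(integer(length(members)), members)
  tab <- table(c(edges$a, edges$b))
  degree[names(tab)] <- as.integer(tab)
  structure(list(nodes = members, edges = edges, threshold = threshold,
                 degree = degree),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network: %d nodes, %d edges, |rho| >= %g>\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

# Canonical unordered edge keys.
edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  a <- pmin(net$edges$a, net$edges$b)
  b <- pmax(net$edges$a, net$edges$b)
  paste(a, b, sep = "\r")
}

#' Similarity of two co-expression networks
#'
#' Jaccard index on unordered edge sets and Pearson correlation of edge
#' weights over the union of edges (absent edge = weight 0).
#'
#' @param a,b `coexpression_network` objects over a shared node universe.
#' @return list(jaccard =, edge_weight_pearson =).
#' @export
network_similarity <- function(a, b) {
  ka <- edge_keys(a); kb <- edge_keys(b)
  union_k <- union(ka, kb)
  if (!length(union_k)) stop("both edge sets are empty; Jaccard undefined")
  jac <- length(intersect(ka, kb)) / length(union_k)
  wa <- setNames(rep(0, length(union_k)), union_k)
  wb <- wa
  wa[ka] <- a$edges$weight
  wb[kb] <- b$edges$weight
  r <- if (length(union_k) >= 2L) cor(wa, wb) else NA_real_
  list(jaccard = jac, edge_weight_pearson = r)
}
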
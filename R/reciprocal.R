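# The relative reciprocal relationship score: each member of a gene (set)
# pair is ranked within the other's genome-wide anticorrelation
# distribution; the squared ranks are summed, penalising weak reciprocity
# (ranks 1 and 200 score worse than ranks 10 and 10).

#' Percentile of a rank within a distribution
#'
#' @param rank Integer rank (1 = most anticorrelated).
#' @param n Number of genes in the distribution.
#' @return Percentile on the 0-100 scale (100 * rank / n).
#' @export
rank_percentile <- function(rank, n) 100 * rank / n

#' Genome-wide anticorrelation rank of a target
#'
#' Correlates `query` against every gene in the matrix; when `target` is
#' a pooled gene set, its summed vector is inserted into the distribution
#' as one additional pseudo-gene (constituent genes stay in by default).
#' Genes are sorted by ascending correlation (ties broken by gene ID);
#' rank 1 is the most anticorrelated.
#'
#' @param target Gene ID or [gene_set()] whose rank is sought.
#' @param query Gene ID whose correlation distribution is computed.
#' @param expr Expression matrix (pseudocounts), genes x samples.
#' @param method Correlation method.
#' @param exclude_members Drop the pooled set's constituent genes from
#'   the distribution (default keeps them).
#' @return list(rank =, percentile =, n =, r = correlation of target).
#' @export
genomewide_rank <- function(target, query, expr,
                            method = c("spearman", "pearson"),
                            exclude_members = FALSE) {
  method <- match.arg(method)
  if (!query %in% rownames(expr)) stop("query gene absent: ", query)
  if (inherits(target, "gene_set")) {
    pooled <- pool_gene_set(expr, target)
    target_id <- paste0("@pooled:", target$name)
    if (exclude_members) {
      expr <- expr[setdiff(rownames(expr), target$members), , drop = FALSE]
    }
    mat <- rbind(expr, pooled)
    rownames(mat)[nrow(mat)] <- target_id
  } else {
    target_id <- as.character(target)
    if (!target_id %in% rownames(expr)) {
      stop("target absent from distribution: ", target_id)
    }
    mat <- expr
  }
  res <- correlate_feature_vs_genes(mat[query, ], mat, method)
  pos <- res$anticorr_rank[match(target_id, res$gene)]
  n <- nrow(mat)
  list(rank = pos, percentile = rank_percentile(pos, n), n = n,
       r = res$r[match(target_id, res$gene)])
}

#' Relative reciprocal relationship score
#'
#' Ranks A within B's genome-wide anticorrelation distribution and B
#' within A's, then sums the squared ranks. Lower scores indicate
#' stronger reciprocal anticorrelation; the minimum is 2 (ranks 1 and 1).
#'
#' @param A Gene ID or [gene_set()] (pooled as a pseudo-gene).
#' @param B Gene ID.
#' @param expr Expression matrix, genes x samples.
#' @inheritParams genomewide_rank
#' @return list of class `reciprocal_score`: rank_A_in_B, rank_B_in_A,
#'   n_genes_A, n_genes_B, percentile_A, percentile_B, score.
#' @export
relative_reciprocal_score <- function(A, B, expr,
                                      method = c("spearman", "pearson"),
                                      exclude_members = FALSE) {
  method <- match.arg(method)
  # A's rank within B's distribution: correlate B against all genes.
  a_in_b <- genomewide_rank(A, B, expr, method, exclude_members)
  # B's rank within A's distribution: correlate pooled A (or gene A)
  # against all genes and locate B.
  a_vec <- if (inherits(A, "gene_set")) pool_gene_set(expr, A) else expr[A, ]
  mat <- if (inherits(A, "gene_set") && exclude_members) {
    expr[setdiff(rownames(expr), A$members), , drop = FALSE]
  } else {
    expr
  }
  res <- correlate_feature_vs_genes(a_vec, mat, method)
  rank_b <- res$anticorr_rank[match(B, res$gene)]
  if (is.na(rank_b)) stop("target absent from distribution: ", B)
  structure(list(A = if (inherits(A, "gene_set")) A$name else A, B = B,
                 rank_A_in_B = a_in_b$rank, rank_B_in_A = rank_b,
                 n_genes_A = nrow(mat), n_genes_B = a_in_b$n,
                 percentile_A = a_in_b$percentile,
                 percentile_B = rank_percentile(rank_b, nrow(mat)),
                 score = reciprocal_score_from_ranks(a_in_b$rank, rank_b)),
            class = "reciprocal_score")
}

#' Reciprocal score from a pair of ranks
#'
#' @param rank_a,rank_b Positive integer ranks.
#' @return rank_a^2 + rank_b^2.
#' @export
reciprocal_score_from_ranks <- function(rank_a, rank_b) {
  if (any(c(rank_a, rank_b) < 1)) stop("ranks must be >= 1")
  as.double(rank_a)^2 + as.double(rank_b)^2
}

#' @export
print.reciprocal_score <- function(x, ...) {
  cat(sprintf(
    "<reciprocal_score %s ~ %s: ranks (%d/%d, %d/%d), score %.0f>\n",
    x$A, x$B, x$rank_A_in_B, x$n_genes_B, x$rank_B_in_A, x$n_genes_A,
    x$score))
  invisible(x)
}

#' Is a pair reciprocally within the top fraction?
#'
#' TRUE iff both percentiles are <= 100 * fraction (boundary included).
#'
#' @param score A `reciprocal_score`.
#' @param fraction Fraction in (0, 1); default the strongest 2.5%.
#' @return Logical flag.
#' @export
reciprocal_top_fraction <- function(score, fraction = 0.025) {
  stopifnot(fraction > 0, fraction < 1)
  score$percentile_A <= 100 * fraction &&
    score$percentile_B <= 100 * fraction
}

#' Paired comparison of reciprocal scores (e.g. tumour vs matched normal)
#'
#' Scores are matched 1:1 by a pairing key (donor). Keys missing from
#' either side are dropped; duplicate matches are reduced to one retained
#' at random under `seed`. A two-sided Wilcoxon signed-rank test is run
#' on the paired scores.
#'
#' @param scores_a,scores_b Numeric score vectors named by pairing key.
#' @param seed Seed for duplicate resolution.
#' @return list(statistic =, p.value =, n_pairs =, pairs = data.frame).
#' @export
matched_pair_comparison <- function(scores_a, scores_b, seed = 1L) {
  dedupe <- function(x) {
    keys <- names(x)
    if (is.null(keys)) stop("scores must be named by pairing key")
    keep <- with_seed(seed, {
      vapply(split(seq_along(keys), keys),
             function(i) if (length(i) == 1L) i else sample(i, 1L),
             integer(1))
    })
    x[keep]
  }
  a <- dedupe(scores_a)
  b <- dedupe(scores_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 5L) stop("need >= 5 matched pairs")
  if (all(a[shared] == b[shared])) {
    return(list(statistic = 0, p.value = 1, n_pairs = length(shared),
                pairs = data.frame(key = shared, a = unname(a[shared]),
                                   b = unname(b[shared]))))
  }
  wt <- suppressWarnings(
    wilcox.test(a[shared], b[shared], paired = TRUE,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_pairs = length(shared),
       pairs = data.frame(key = shared, a = unname(a[shared]),
                          b = unname(b[shared])))
}

#' Regress a covariate on reciprocal scores across cohorts
#'
#' Ordinary least squares of the covariate on the (optionally logged)
#' score across cohorts; used e.g. to relate relationship strength to a
#' proliferative index.
#'
#' @param scores Per-cohort numeric scores.
#' @param covariate Per-cohort numeric covariate.
#' @param log_score Regress on log(score) (default TRUE; scores span
#'   orders of magnitude).
#' @return list(r_squared =, slope =, p.value =, n =).
#' @export
score_vs_covariate <- function(scores, covariate, log_score = TRUE) {
  keep <- complete.cases(scores, covariate)
  scores <- scores[keep]; covariate <- covariate[keep]
  if (length(scores) < 3L) stop("need >= 3 cohorts")
  if (length(unique(covariate)) == 1L) stop("covariate is constant")
  x <- if (log_score) log(scores) else scores
  fit <- lm(covariate ~ x)
  s <- summary(fit)
  list(r_squared = s$r.squared, slope = unname(coef(fit)[2L]),
       p.value = s$coefficients[2L, 4L], n = length(scores))
}
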
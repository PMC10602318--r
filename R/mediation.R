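# Mutation classification, resampled group-median comparison, nested
# linear models distinguishing regulatory architectures, Fisher TF-binding
# enrichment, and additive two-way ANOVA.

#' Default qualifying mutation consequence classes
#'
#' Missense, nonsense, frame-shifting insertion, in-frame deletion and
#' frame-shift deletion (MAF-style labels, matched case-insensitively).
#'
#' @export
qualifying_consequences <- c("Missense_Mutation", "Nonsense_Mutation",
                             "Frame_Shift_Ins", "In_Frame_Del",
                             "Frame_Shift_Del")

#' Classify samples by mutation status of a gene
#'
#' A sample is `mutant` if it has at least one qualifying call in the
#' gene, `wildtype` if it appears in the call table for other genes but
#' has no qualifying call in the gene, and `unknown` if it has no calls
#' at all (absence of evidence is never treated as wild type).
#'
#' @param calls data.frame with columns sample, gene, consequence.
#' @param gene Gene to test (e.g. "RB1").
#' @param classes Qualifying consequence classes (case-insensitive).
#' @param samples Optional sample universe; samples absent from `calls`
#'   are reported as `unknown`.
#' @return Named factor with levels mutant/wildtype/unknown.
#' @export
classify_mutants <- function(calls, gene,
                             classes = qualifying_consequences,
                             samples = NULL) {
  if (!nrow(calls)) stop("empty mutation call table")
  needed <- c("sample", "gene", "consequence")
  if (!all(needed %in% colnames(calls))) {
    stop("calls must have columns: ", paste(needed, collapse = ", "))
  }
  samples <- samples %||% unique(calls$sample)
  qual <- calls$gene == gene &
    tolower(calls$consequence) %in% tolower(classes)
  mutants <- unique(calls$sample[qual])
  called <- unique(calls$sample)
  status <- ifelse(samples %in% mutants, "mutant",
                   ifelse(samples %in% called, "wildtype", "unknown"))
  setNames(factor(status, levels = c("mutant", "wildtype", "unknown")),
           samples)
}

# Build the pooled resampled index set shared by the resampled-median and
# nested-model procedures: per iteration, n_per_group mutant and
# n_per_group wild-type samples from each admitted cohort.
resample_status_indices <- function(status, cohort, n_per_group, n_iter,
                                    seed) {
  mut <- status == "mutant" | status == TRUE
  wt <- status == "wildtype" | status == FALSE
  admitted <- character()
  for (ch in unique(cohort)) {
    if (sum(mut & cohort == ch) >= n_per_group &&
        sum(wt & cohort == ch) >= n_per_group) {
      admitted <- c(admitted, ch)
    }
  }
  if (!length(admitted)) {
    stop("no cohort with >= ", n_per_group, " samples in both groups")
  }
  with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      mi <- wi <- integer()
      for (ch in admitted) {
        mi <- c(mi, sample(which(mut & cohort == ch), n_per_group))
        wi <- c(wi, sample(which(wt & cohort == ch), n_per_group))
      }
      list(mutant = mi, wildtype = wi)
    })
  })
}

#' Resampled cross-cohort group medians
#'
#' Per iteration, samples `n_per_group` mutant and `n_per_group`
#' wild-type samples from each admitted cohort (cohorts need both groups
#' at that size), pools them across cohorts, and records each group's
#' median rank-percentile. The two distributions of medians are compared
#' with a two-sample t-test.
#'
#' Note: treating the `n_iter` resampled medians as independent
#' observations inherits pseudo-replication from the published procedure;
#' the returned `median_difference` (one number per run) is the honest
#' single-estimate alternative for use across outer replicates.
#'
#' @param values Per-sample numeric vector (rank percentiles).
#' @param status Per-sample status: logical (TRUE = mutant) or factor
#'   with levels mutant/wildtype.
#' @param cohort Per-sample cohort label.
#' @param n_per_group Samples per group per cohort per iteration.
#' @param n_iter Number of resampling iterations.
#' @param seed Integer seed.
#' @return list: mutant_medians, wildtype_medians (length n_iter),
#'   statistic, p.value, median_difference.
#' @export
resampled_group_medians <- function(values, status, cohort,
                                    n_per_group = 10L, n_iter = 1000L,
                                    seed = 1L) {
  idx <- resample_status_indices(status, cohort, n_per_group, n_iter,
                                 seed)
  mm <- vapply(idx, function(i) median(values[i$mutant]), numeric(1))
  wm <- vapply(idx, function(i) median(values[i$wildtype]), numeric(1))
  tt <- t.test(mm, wm)
  list(mutant_medians = mm, wildtype_medians = wm,
       statistic = unname(tt$statistic), p.value = tt$p.value,
       median_difference = median(mm) - median(wm))
}

#' Nested models for mutation-status mediation
#'
#' Builds one pooled dataset from the resampled mutant/wild-type draws
#' and fits four least-squares models on the identical sample set:
#' HMT ~ status, HMT ~ status + NNMT, NNMT ~ status, and
#' NNMT ~ status + HMT. The t-values of the status coefficient are
#' extracted and attenuation ratios computed as
#' 1 - |t_adjusted| / |t_marginal|: attenuation near 1 for a response
#' means the counterpart expression fully accounts for the mutation
#' effect on it (a chain architecture); attenuation near 0 for both
#' means two independent arms.
#'
#' @param hmt_values,sink_values Per-sample numeric vectors (typically
#'   rank percentiles of pooled-HMT and sink expression).
#' @inheritParams resampled_group_medians
#' @return list of class `nested_model_result`: t_hmt_marginal,
#'   t_hmt_adjusted, t_sink_marginal, t_sink_adjusted, attenuation_hmt,
#'   attenuation_sink, n.
#' @export
nested_rb_models <- function(hmt_values, sink_values, status, cohort,
                             n_per_group = 10L, n_iter = 1000L,
                             seed = 1L) {
  idx <- resample_status_indices(status, cohort, n_per_group, n_iter,
                                 seed)
  rows <- unlist(lapply(idx, function(i) c(i$mutant, i$wildtype)))
  is_mut <- unlist(lapply(idx, function(i) {
    rep(c(TRUE, FALSE), c(length(i$mutant), length(i$wildtype)))
  }))
  d <- data.frame(hmt = hmt_values[rows], sink = sink_values[rows],
                  status = is_mut)
  if (sd(d$hmt) == 0 || sd(d$sink) == 0 ||
      abs(cor(d$hmt, d$sink)) > 1 - 1e-10) {
    stop("collinear or constant inputs")
  }
  tval <- function(fml) {
    summary(lm(fml, data = d))$coefficients["statusTRUE", "t value"]
  }
  t_hm <- tval(hmt ~ status)
  t_ha <- tval(hmt ~ status + sink)
  t_sm <- tval(sink ~ status)
  t_sa <- tval(sink ~ status + hmt)
  structure(list(t_hmt_marginal = t_hm, t_hmt_adjusted = t_ha,
                 t_sink_marginal = t_sm, t_sink_adjusted = t_sa,
                 attenuation_hmt = 1 - abs(t_ha) / abs(t_hm),
                 attenuation_sink = 1 - abs(t_sa) / abs(t_sm),
                 n = nrow(d)),
            class = "nested_model_result")
}

#' @export
print.nested_model_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<nested_model_result: status t on HMT %.2f -> %.2f (att %.2f); ",
    "on sink %.2f -> %.2f (att %.2f)>\n"),
    x$t_hmt_marginal, x$t_hmt_adjusted, x$attenuation_hmt,
    x$t_sink_marginal, x$t_sink_adjusted, x$attenuation_sink))
  invisible(x)
}

#' Classify the regulatory architecture from attenuation signatures
#'
#' "chain" when the mutation effect on the sink is absorbed by HMT
#' expression but not vice versa; "independent" when neither coefficient
#' attenuates; "shared" / "reverse_chain" for the remaining signatures.
#'
#' @param result A `nested_model_result`.
#' @param threshold Attenuation cut-off (default 0.5).
#' @return One of "chain", "independent", "reverse_chain", "shared".
#' @export
classify_architecture <- function(result, threshold = 0.5) {
  hi_sink <- result$attenuation_sink >= threshold
  hi_hmt <- result$attenuation_hmt >= threshold
  if (hi_sink && !hi_hmt) "chain"
  else if (!hi_sink && !hi_hmt) "independent"
  else if (hi_hmt && !hi_sink) "reverse_chain"
  else "shared"
}

#' Fisher enrichment of a gene set among TF-bound genes
#'
#' For each transcription factor's bound-gene list, a 2x2 table of
#' bound/unbound by in-set/out-of-set over the universe is tested with a
#' two-sided Fisher exact test. Both the sample odds ratio (Haldane 0.5
#' correction on zero cells) and the conditional-MLE estimate are
#' reported, with raw p and BH q.
#'
#' @param bound_sets Named list: per-TF character vectors of bound genes.
#' @param query [gene_set()] or character vector (must be within the
#'   universe).
#' @param universe Character vector of all genes considered.
#' @return data.frame: tf, n_bound_in_set, odds_ratio (sample),
#'   odds_ratio_cmle, p, q.
#' @export
tf_enrichment <- function(bound_sets, query, universe) {
  if (!length(universe)) stop("empty universe")
  qset <- if (inherits(query, "gene_set")) query$members else query
  if (!all(qset %in% universe)) stop("query must be a subset of universe")
  rows <- lapply(names(bound_sets), function(tf) {
    bound <- intersect(bound_sets[[tf]], universe)
    a <- length(intersect(bound, qset))
    b <- length(setdiff(bound, qset))
    cc <- length(setdiff(qset, bound))
    dd <- length(universe) - a - b - cc
    tab <- matrix(c(a, b, cc, dd), 2L, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    sample_or <- if (any(tab == 0)) {
      ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * dd) / (b * cc)
    }
    data.frame(tf = tf, n_bound_in_set = a, odds_ratio = sample_or,
               odds_ratio_cmle = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out
}

#' Additive two-way ANOVA with type-II sums of squares
#'
#' No-interaction two-way ANOVA suitable for unbalanced designs: each
#' factor's sum of squares is the reduction in residual SS when it is
#' added to the model already containing the other factor, tested
#' against the residual mean square of the full additive model.
#'
#' @param y Numeric response.
#' @param factor_a,factor_b Factors with >= 2 levels each.
#' @return data.frame: term, df, sum_sq, f, p.
#' @export
two_way_anova <- function(y, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs >= 2 levels")
  }
  d <- data.frame(y = y, a = a, b = b)
  X <- model.matrix(~ a + b, d)
  if (qr(X)$rank < ncol(X)) stop("factors are confounded (aliased)")
  full <- lm(y ~ a + b, d)
  df_res <- full$df.residual
  if (df_res < 1L) stop("no residual degrees of freedom")
  if (var(y) < .Machine$double.eps * (mean(y)^2 + 1)) {
    # Constant response: no evidence either way.
    return(data.frame(term = c("a", "b"),
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L),
                      sum_sq = c(0, 0), f = c(0, 0), p = c(1, 1)))
  }
  rss <- function(fml) sum(residuals(lm(fml, d))^2)
  rss_full <- rss(y ~ a + b)
  ss_a <- rss(y ~ b) - rss_full
  ss_b <- rss(y ~ a) - rss_full
  mse <- rss_full / df_res
  if (mse == 0) {
    # Degenerate (e.g. constant response): report no evidence either way.
    return(data.frame(term = c("a", "b"),
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L),
                      sum_sq = c(ss_a, ss_b), f = c(0, 0), p = c(1, 1)))
  }
  f_a <- (ss_a / (nlevels(a) - 1L)) / mse
  f_b <- (ss_b / (nlevels(b) - 1L)) / mse
  data.frame(
    term = c("a", "b"),
    df = c(nlevels(a) - 1L, nlevels(b) - 1L),
    sum_sq = c(ss_a, ss_b),
    f = c(f_a, f_b),
    p = c(stats::pf(f_a, nlevels(a) - 1L, df_res, lower.tail = FALSE),
          stats::pf(f_b, nlevels(b) - 1L, df_res, lower.tail = FALSE)))
}
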
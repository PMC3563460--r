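# Evaluation statistics on the validation set, paired method comparison
# with Bonferroni control, and marker-effect distribution summaries.

#' Evaluate predictions on a validation set
#'
#' Computes, from validation observations and predictions only:
#' predictive ability (Pearson correlation `r(y, yhat)`), bias
#' (`mean(yhat - y) / phenotypic_sd`, so under-prediction is negative),
#' inflation (slope of the regression of `y` on `yhat`; below 1 means
#' over-dispersed predictions), NRMSE (root-mean-squared error divided by
#' the range of the observed values), and accuracy `r / sqrt(h2)`.
#' When the predictions have zero standard deviation the correlation-based
#' statistics are undefined (`NA`) and the others are still computed — the
#' situation of the pedigree-only baseline under across-family splitting.
#'
#' @param y_obs observed validation phenotypes (>= 3).
#' @param y_pred predicted values, same length.
#' @param phenotypic_sd SD used to normalise the bias; defaults to
#'   `sd(y_obs)`.
#' @param h2 heritability for the accuracy denominator (`NA` allowed).
#' @return one-row data frame: `predictive_ability`, `bias`, `inflation`,
#'   `nrmse`, `accuracy`, `n_val`.
#' @export
evaluate_predictions <- function(y_obs, y_pred, phenotypic_sd = stats::sd(y_obs),
                                 h2 = NA_real_) {
  stop_unless(length(y_obs) == length(y_pred), "length mismatch")
  stop_unless(length(y_obs) >= 3, "need at least three validation animals")
  sd_pred <- stats::sd(y_pred)
  r <- if (sd_pred > 0) stats::cor(y_obs, y_pred) else NA_real_
  slope <- if (sd_pred > 0) stats::cov(y_obs, y_pred) / stats::var(y_pred) else NA_real_
  data.frame(predictive_ability = r,
             bias = mean(y_pred - y_obs) / phenotypic_sd,
             inflation = slope,
             nrmse = sqrt(mean((y_pred - y_obs)^2)) / diff(range(y_obs)),
             accuracy = r / sqrt(h2),
             n_val = length(y_obs))
}

#' Pairwise paired t-tests on per-replicate predictive abilities
#'
#' For every pair of methods, a paired t-test over replicates (the same
#' partitions are served to every method) at level `alpha`, Bonferroni
#' corrected for the number of pairs.  Pairs with identical per-replicate
#' values, or with zero variance of the paired differences, carry no
#' evidence of a difference and are reported as `p = 1` with a degenerate
#' flag.  A letter display groups methods that are mutually
#' non-significant (greedy clique cover in mean order).
#'
#' @param report data frame with columns `method`, `replicate`,
#'   `predictive_ability`.
#' @param alpha familywise level, default 0.05.
#' @return list with `pairs` (data frame `method1, method2, p_raw,
#'   p_bonferroni, significant, degenerate`), `letters` (named character),
#'   `means` (named, sorted decreasing).
#' @export
compare_methods <- function(report, alpha = 0.05) {
  methods <- unique(report$method)
  stop_unless(length(methods) >= 2, "need at least two methods")
  wide <- lapply(methods, function(m) {
    sub <- report[report$method == m, ]
    stats::setNames(sub$predictive_ability, sub$replicate)
  })
  names(wide) <- methods
  combs <- utils::combn(methods, 2, simplify = FALSE)
  n_pairs <- length(combs)
  rows <- lapply(combs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    reps <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
    if (length(reps) < 2)
      return(data.frame(method1 = pr[1], method2 = pr[2], p_raw = NA_real_,
                        degenerate = TRUE))
    d <- a[reps] - b[reps]
    if (stats::sd(d) < 1e-10 * (stats::sd(a[reps]) + 1e-12))
      return(data.frame(method1 = pr[1], method2 = pr[2],
                        p_raw = if (all(d == 0)) 1 else 0, degenerate = TRUE))
    data.frame(method1 = pr[1], method2 = pr[2],
               p_raw = stats::t.test(a[reps], b[reps], paired = TRUE)$p.value,
               degenerate = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_bonferroni <- pmin(pairs$p_raw * n_pairs, 1)
  pairs$significant <- !is.na(pairs$p_bonferroni) & pairs$p_bonferroni <= alpha
  means <- sort(vapply(wide, function(v) mean(v, na.rm = TRUE), numeric(1)),
                decreasing = TRUE)
  list(pairs = pairs, letters = significance_letters(pairs, names(means)),
       means = means)
}

# Greedy clique cover over the non-significant-pair graph, methods taken in
# mean order; methods in the same clique share a letter.
significance_letters <- function(pairs, method_order) {
  differs <- function(m1, m2) {
    hit <- (pairs$method1 == m1 & pairs$method2 == m2) |
      (pairs$method1 == m2 & pairs$method2 == m1)
    any(pairs$significant[hit], na.rm = TRUE)
  }
  groups <- list()
  for (m in method_order) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], differs, logical(1), m2 = m))) {
        groups[[gi]] <- c(groups[[gi]], m)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- m
  }
  out <- stats::setNames(rep("", length(method_order)), method_order)
  for (gi in seq_along(groups))
    for (m in groups[[gi]])
      out[m] <- paste0(out[m], letters[gi])
  out
}

#' Summaries of an estimated marker-effect distribution
#'
#' Markers are ranked by per-locus variance `2 p_i (1 - p_i) g_i^2`;
#' `t_x` is the fraction of the summed per-locus variance contributed by
#' the top `x` markers.  Also reports the count of markers with a nonzero
#' estimated effect and the excess kurtosis of the effect distribution.
#'
#' @param fit a [marker_effects()].
#' @param x_list top-marker counts, default `c(1000, 500, 100, 20)`
#'   (capped at p).
#' @return list with `t_x` (named), `n_nonzero`, `excess_kurtosis`;
#'   `t_x` is `NA` when the total per-locus variance is zero.
#' @export
effect_distribution_summary <- function(fit, x_list = c(1000, 500, 100, 20)) {
  v <- fit$per_locus_variance
  stop_unless(!is.null(v), "fit lacks per-locus variances (allele_freq missing)")
  total <- sum(v)
  vs <- sort(v, decreasing = TRUE)
  t_x <- vapply(x_list, function(x) {
    if (total <= 0) NA_real_ else sum(vs[seq_len(min(x, length(vs)))]) / total
  }, numeric(1))
  names(t_x) <- paste0("t", x_list)
  g <- fit$g
  m2 <- mean((g - mean(g))^2)
  kurt <- if (m2 > 0) mean((g - mean(g))^4) / m2^2 - 3 else NA_real_
  list(t_x = t_x, n_nonzero = sum(g != 0), excess_kurtosis = kurt)
}
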
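# Two-stage subset-selection estimators: significance screening with
# Benjamini-Yekutieli control (SS_BY) and screening on estimated per-locus
# variance contributions (SS_ABS).

# Stage-2 joint ridge refit of a selected marker subset; k (and hence
# lambda) is recomputed over the selected loci so the genetic variance is
# attributed to the retained markers only.
refit_selected <- function(X, y, selected, spec, method, allele_freq, extra) {
  g <- numeric(ncol(X))
  names(g) <- colnames(X)
  if (!any(selected)) {
    return(marker_effects(mu = mean(y), g = g, method = method,
                          allele_freq = allele_freq, center = 2 * allele_freq,
                          selected = selected,
                          extra = c(extra, list(empty_selection = TRUE))))
  }
  ps <- allele_freq[selected]
  spec_s <- ridge_spec(spec$sigma2_u, spec$sigma2_e, allele_freq = ps)
  sub <- rr_gblup_svd(X[, selected, drop = FALSE], y, spec = spec_s)
  g[selected] <- sub$g
  marker_effects(mu = sub$mu, g = g, method = method,
                 allele_freq = allele_freq, center = 2 * allele_freq,
                 lambda = spec_s$lambda, selected = selected,
                 extra = c(extra, list(empty_selection = FALSE)))
}

#' Subset selection by single-marker significance (SS_BY)
#'
#' Stage 1 regresses the phenotype on each marker separately (simple linear
#' regression with intercept; the p-value is that of the slope t-statistic)
#' and adjusts the p-values by the Benjamini-Yekutieli step-up procedure,
#' which controls the false-discovery rate under arbitrary dependence via
#' the harmonic-sum factor `c(m) = sum_{j<=m} 1/j`.  Markers with adjusted
#' p <= `alpha` are refit jointly as random effects in stage 2.  When no
#' marker passes, the fit is flagged (`extra$empty_selection`) and
#' predictions reduce to the intercept.
#'
#' @param X raw dosage matrix.
#' @param y phenotype vector.
#' @param spec a [ridge_spec()] providing the stage-2 variance components.
#' @param alpha FDR level, default 0.01.
#' @return A [marker_effects()]; `extra$p_raw` and `extra$p_adjusted` carry
#'   the stage-1 scan.
#' @export
ss_by <- function(X, y, spec, alpha = 0.01) {
  n <- nrow(X)
  stop_unless(n > 2, "need more than two records")
  sdx <- apply(X, 2, stats::sd)
  sdy <- stats::sd(y)
  r <- rep(0, ncol(X))
  ok <- sdx > 0 & sdy > 0
  if (any(ok)) r[ok] <- suppressWarnings(stats::cor(X[, ok, drop = FALSE], y))
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- ifelse(ok, 2 * stats::pt(-abs(tstat), df = n - 2), 1)
  p_adj <- stats::p.adjust(p_raw, method = "BY")
  selected <- p_adj <= alpha & ok
  refit_selected(X, y, selected, spec, "ss_by",
                 allele_freq = col_allele_freq(X),
                 extra = list(p_raw = p_raw, p_adjusted = p_adj,
                              alpha = alpha))
}

#' Subset selection by per-locus variance contribution (SS_ABS)
#'
#' Stage 1 fits the full ridge model ([rr_gblup_svd()]) and computes each
#' locus's contribution to the genetic variance,
#' `v_i = 2 p_i (1 - p_i) g_i^2`; loci with `v_i` strictly above
#' `mean(v) + sd_mult * sd(v)` are refit jointly in stage 2.
#'
#' @inheritParams ss_by
#' @param sd_mult upper-tail multiplier, default 1.5.
#' @return A [marker_effects()]; `extra$stage1` keeps the full ridge fit.
#' @export
ss_abs <- function(X, y, spec, sd_mult = 1.5) {
  stage1 <- rr_gblup_svd(X, y, spec = spec)
  v <- stage1$per_locus_variance
  thr <- mean(v) + sd_mult * stats::sd(v)
  selected <- is.finite(thr) & v > thr
  refit_selected(X, y, selected, spec, "ss_abs",
                 allele_freq = stage1$allele_freq,
                 extra = list(stage1 = stage1, threshold = thr,
                              sd_mult = sd_mult))
}
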
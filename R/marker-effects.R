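# Common container for marker-effect fits and prediction.

#' Construct a marker-effects fit
#'
#' Shared result container for every marker-effect estimator: intercept,
#' per-marker additive effects on the dosage scale, the selection indicator
#' for subset/sparse methods and the per-locus variance
#' `2 p_i (1 - p_i) g_i^2` implied by the allele frequencies.
#'
#' @param mu intercept.
#' @param g named effect vector (length p).
#' @param method method label.
#' @param allele_freq per-marker allele frequency `p_i` used for centring
#'   and per-locus variances.
#' @param center per-marker centring constants subtracted from dosages
#'   before fitting (usually `2 p_i`), or `NULL` for no centring.
#' @param lambda shrinkage ratio where applicable.
#' @param selected logical vector of selected markers (default `g != 0`).
#' @param extra list of method-specific results (posterior summaries,
#'   hyperparameter estimates, flags).
#' @return Object of class `marker_effects`.
#' @export
marker_effects <- function(mu, g, method, allele_freq = NULL, center = NULL,
                           lambda = NULL, selected = NULL, extra = list()) {
  g <- drop(g)
  plv <- if (!is.null(allele_freq)) 2 * allele_freq * (1 - allele_freq) * g^2
  structure(list(mu = mu, g = g, method = method, allele_freq = allele_freq,
                 center = center, lambda = lambda,
                 selected = selected %||% (g != 0),
                 per_locus_variance = plv, extra = extra),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("<marker_effects: %s> p=%d, %d nonzero, mu=%.4g\n",
              x$method, length(x$g), sum(x$g != 0), x$mu))
  invisible(x)
}

#' Predict phenotypes from a marker-effects fit
#'
#' @param object a [marker_effects()] fit.
#' @param newdata raw dosage matrix (animals x markers, same marker set and
#'   coding as the training data) or a [genotype_matrix()].
#' @param ... unused.
#' @return numeric vector `mu + (X - center) %*% g`.
#' @export
predict.marker_effects <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "genotype_matrix")) newdata$dosages else as.matrix(newdata)
  stop_unless(ncol(X) == length(object$g), "marker count mismatch")
  Xc <- if (!is.null(object$center)) sweep(X, 2, object$center) else X
  drop(object$mu + Xc %*% object$g)
}
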
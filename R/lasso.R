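# L1-penalised marker effects with the penalty chosen by internal
# cross-validation.

#' LASSO marker effects with internal 10-fold cross-validation
#'
#' Fits the L1-penalised least-squares path (via glmnet, unstandardised so
#' the constraint applies to the marker effects on the dosage scale) and
#' picks the penalty minimising the internal k-fold cross-validation error
#' computed on the training set only.
#'
#' @param X raw dosage matrix (training/reference animals).
#' @param y phenotype vector.
#' @param folds number of internal CV folds, default 10.
#' @param seed optional seed controlling the fold assignment.
#' @return A [marker_effects()]; `extra$lambda_glmnet` is the chosen
#'   penalty on the glmnet scale (objective `RSS/(2n) + lambda ||g||_1`),
#'   `extra$n_nonzero` the selected-marker count and `extra$cvfit` the
#'   `cv.glmnet` object.
#' @export
lasso_cv <- function(X, y, folds = 10, seed = NULL) {
  n <- nrow(X)
  stop_unless(n >= folds, "need at least as many records as folds")
  foldid <- if (!is.null(seed)) {
    with_seed(seed, sample(rep_len(seq_len(folds), n)))
  } else sample(rep_len(seq_len(folds), n))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = folds, foldid = foldid,
                          standardize = FALSE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  g <- co[-1]
  names(g) <- colnames(X)
  marker_effects(mu = co[1], g = g, method = "lasso",
                 allele_freq = col_allele_freq(X), center = NULL,
                 extra = list(lambda_glmnet = cv$lambda.min,
                              n_nonzero = sum(g != 0), cvfit = cv))
}
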
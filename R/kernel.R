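# Kernel and ensemble predictors: Gaussian-kernel RKHS regression (Gibbs),
# support vector regression and random-forest regression.

#' Gaussian kernel from genotype dosages
#'
#' `K_h(x_i, x_j) = exp(-h d_ij)` with `d_ij` the squared Euclidean
#' distance between the raw dosage vectors and bandwidth `h = 2 / d*`,
#' where `d*` is the mean off-diagonal `d_ij` of the reference set.  The
#' cross kernel between other animals and the reference set uses the same
#' `h` (and the reference `d*`).
#'
#' @param X_ref reference dosage matrix (n_ref x p).
#' @param X_other optional matrix of further animals on the same marker
#'   set; fills the `K_cross` block.
#' @return Object of class `kernel_matrix`: `K` (n_ref x n_ref, unit
#'   diagonal), `K_cross` (n_other x n_ref or NULL), `h`, `d_star`.
#' @export
gaussian_kernel <- function(X_ref, X_other = NULL) {
  stop_unless(is.null(X_other) || ncol(X_other) == ncol(X_ref),
              "marker sets must match")
  d2 <- sq_dist(X_ref, X_ref)
  n <- nrow(X_ref)
  d_star <- sum(d2) / (n * (n - 1))  # off-diagonal mean; diagonal is zero
  stop_unless(d_star > 0, "all reference genotypes identical: d* = 0")
  h <- 2 / d_star
  K <- exp(-h * d2)
  K_cross <- if (!is.null(X_other)) exp(-h * sq_dist(X_other, X_ref))
  structure(list(K = K, K_cross = K_cross, h = h, d_star = d_star),
            class = "kernel_matrix")
}

# pairwise squared Euclidean distances between rows of A and rows of B
sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Bayesian RKHS regression via Gibbs sampling
#'
#' Fits `y = mu + K alpha + e` with `alpha ~ N(0, K sigma2_alpha)` and
#' `e ~ N(0, I sigma2_e)`, scaled inverse-chi-square priors on both
#' variances.  The sampler works in the eigenbasis of `K`: with
#' `K = U diag(lambda) U'` and `t = U' alpha`, the coefficients `t` have
#' independent priors and an orthogonal design, so their full conditional
#' is diagonal and the whole vector is drawn in one vectorised step per
#' iteration.  Eigenvalues in `(-1e-8, 0]` are floored to zero (those
#' directions are dropped); eigenvalues below `-1e-8` are rejected.
#'
#' @param kern a [kernel_matrix()] (use `X_other` for validation animals),
#'   or a plain PSD matrix.
#' @param y phenotypes of the reference animals.
#' @param chain a [chain_settings()].
#' @param nu prior degrees of freedom, default 4.2.
#' @param genetic_share prior variance split used for the prior scales,
#'   default 0.5.
#' @param fix_sigma_alpha,fix_sigma_e freeze a variance (conjugate
#'   closed-form checks), default `NULL` = sample.
#' @return list with `mu`, `alpha` (posterior means), `predictions`
#'   (posterior-mean validation predictions when the kernel has a cross
#'   block), `sigma2_alpha`, `sigma2_e`, `trace`, `mcse_alpha` (batch-mean
#'   Monte-Carlo standard errors of `alpha`), `fitted`.
#' @export
rkhs_gibbs <- function(kern, y, chain = chain_settings(), nu = 4.2,
                       genetic_share = 0.5, fix_sigma_alpha = NULL,
                       fix_sigma_e = NULL) {
  K <- if (inherits(kern, "kernel_matrix")) kern$K else as.matrix(kern)
  K_cross <- if (inherits(kern, "kernel_matrix")) kern$K_cross else NULL
  n <- length(y)
  stop_unless(nrow(K) == n, "kernel dimension must match y")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  stop_unless(min(eg$values) > -1e-8, "kernel is not positive semidefinite")
  keep <- eg$values > 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  m <- length(lam)
  with_seed(chain$seed, {
    vy <- stats::var(y)
    sa0 <- fix_sigma_alpha %||% (genetic_share * vy / mean(lam))
    se0 <- fix_sigma_e %||% ((1 - genetic_share) * vy)
    Sa <- sa0 * (nu + 2) / nu
    Se <- se0 * (nu + 2) / nu
    sigma2_a <- sa0
    sigma2_e <- se0
    mu <- mean(y)
    tt <- numeric(m)
    Uty <- crossprod(U, y)          # m-vector, fixed
    Ut1 <- crossprod(U, rep(1, n))  # for the mu-dependent part

    n_keep <- chain$n_iter - chain$burn_in
    n_batch <- max(min(20L, n_keep %/% 10L), 1L)
    batch_of <- rep(seq_len(n_batch), length.out = n_keep)
    t_batch <- matrix(0, m, n_batch)
    t_sum <- numeric(m); mu_sum <- 0; kept <- 0L
    tr_len <- n_keep %/% chain$thin
    trace <- matrix(NA_real_, tr_len, 2,
                    dimnames = list(NULL, c("sigma2_alpha", "sigma2_e")))
    ti <- 0L
    for (it in seq_len(chain$n_iter)) {
      # t | rest: orthogonal design W = U diag(lam), prior t_i ~ N(0, lam_i sa)
      z <- drop(Uty - mu * Ut1)
      prec <- lam^2 / sigma2_e + 1 / (lam * sigma2_a)
      mean_t <- (lam * z / sigma2_e) / prec
      tt <- stats::rnorm(m, mean_t, sqrt(1 / prec))
      fitted_g <- drop(U %*% (lam * tt))
      resid <- y - fitted_g
      mu <- stats::rnorm(1, mean(resid), sqrt(sigma2_e / n))
      e <- resid - mu
      if (is.null(fix_sigma_alpha))
        sigma2_a <- (nu * Sa + sum(tt^2 / lam)) / stats::rchisq(1, nu + m)
      if (is.null(fix_sigma_e))
        sigma2_e <- (nu * Se + sum(e^2)) / stats::rchisq(1, nu + n)
      if (it > chain$burn_in) {
        kept <- kept + 1L
        t_sum <- t_sum + tt
        t_batch[, batch_of[kept]] <- t_batch[, batch_of[kept]] + tt
        mu_sum <- mu_sum + mu
        if (kept %% chain$thin == 0L) {
          ti <- ti + 1L
          trace[ti, ] <- c(sigma2_a, sigma2_e)
        }
      }
    }
    t_mean <- t_sum / kept
    alpha <- drop(U %*% t_mean)
    mu_hat <- mu_sum / kept
    batch_n <- tabulate(batch_of[seq_len(kept)], n_batch)
    alpha_b <- U %*% sweep(t_batch, 2, pmax(batch_n, 1), "/")
    mcse_alpha <- sqrt(apply(alpha_b, 1, stats::var) / n_batch)
    preds <- if (!is.null(K_cross)) drop(mu_hat + K_cross %*% alpha)
    list(mu = mu_hat, alpha = alpha, predictions = preds,
         sigma2_alpha = mean(trace[, 1]), sigma2_e = mean(trace[, 2]),
         trace = trace, mcse_alpha = mcse_alpha,
         fitted = drop(mu_hat + K %*% alpha))
  })
}

#' Support vector regression on genotype dosages
#'
#' Epsilon-insensitive SVR with a radial-basis kernel; the regularisation
#' parameter defaults to `C = 1` and `gamma`/`epsilon` keep the library
#' defaults (`1/p`, 0.1).  Dosages share a common scale so columns are not
#' rescaled.
#'
#' @param X_ref,y_ref training dosages and phenotypes.
#' @param X_val validation dosages.
#' @param cost regularisation parameter `C`, default 1.
#' @param gamma RBF bandwidth, default `1 / ncol(X_ref)`.
#' @param epsilon insensitivity tube, default 0.1.
#' @return list with `predictions` (validation) and the fitted `model`.
#' @export
svr_fit <- function(X_ref, y_ref, X_val, cost = 1,
                    gamma = 1 / ncol(X_ref), epsilon = 0.1) {
  stop_unless(!anyNA(X_ref) && !anyNA(X_val), "SVR requires complete dosages")
  if (stats::sd(y_ref) == 0) {  # constant response: no support vectors
    return(list(predictions = rep(y_ref[1], nrow(X_val)), model = NULL))
  }
  model <- e1071::svm(x = X_ref, y = y_ref, type = "eps-regression",
                      kernel = "radial", cost = cost, gamma = gamma,
                      epsilon = epsilon, scale = FALSE)
  list(predictions = unname(stats::predict(model, X_val)), model = model)
}

#' Random-forest regression on genotype dosages
#'
#' Regression forest over the marker matrix; `mtry` defaults to the
#' regression convention `p / 3`.  The out-of-bag mean-squared error is
#' returned alongside the validation predictions.
#'
#' @param X_ref,y_ref training dosages and phenotypes.
#' @param X_val validation dosages.
#' @param n_trees number of trees, default 1000.
#' @param mtry candidate features per split, default `max(floor(p/3), 1)`.
#' @param seed RNG seed (forests are stochastic), default 1.
#' @return list with `predictions`, `oob_mse`, `importance` (named,
#'   impurity-based), `model`.
#' @export
rf_fit <- function(X_ref, y_ref, X_val, n_trees = 1000,
                   mtry = max(floor(ncol(X_ref) / 3), 1), seed = 1L) {
  df <- data.frame(y = y_ref, X_ref, check.names = FALSE)
  model <- ranger::ranger(dependent.variable.name = "y", data = df,
                          num.trees = n_trees, mtry = min(mtry, ncol(X_ref)),
                          importance = "impurity", seed = seed,
                          num.threads = 1, verbose = FALSE)
  preds <- stats::predict(model, data.frame(X_val, check.names = FALSE),
                          num.threads = 1)$predictions
  list(predictions = unname(preds), oob_mse = model$prediction.error,
       importance = model$variable.importance, model = model)
}
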
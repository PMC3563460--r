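# Bayesian mixture regression of marker effects: BayesCpi (exclusion
# probability pi estimated) and BayesC (pi fixed), by single-site Gibbs
# sampling with residual updates.

#' Gibbs chain settings
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded, must be `< n_iter`.
#' @param thin keep every `thin`-th post-burn-in draw for traces.
#' @param seed RNG seed for reproducible chains.
#' @return Object of class `chain_settings`.
#' @export
chain_settings <- function(n_iter = 5000, burn_in = 500, thin = 1, seed = 1L) {
  stop_unless(burn_in < n_iter, "burn_in must be smaller than n_iter")
  stop_unless(thin >= 1, "thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_settings")
}

#' BayesCpi marker effects by Gibbs sampling
#'
#' Mixture model: each marker effect `a_j ~ N(0, sigma2_a)` enters the
#' model through an indicator `I_j` with `P(I_j = 1) = 1 - pi`; scaled
#' inverse-chi-square priors on `sigma2_a` and `sigma2_e` and a uniform
#' prior on `pi`, whose full conditional is then
#' `Beta(#excluded + 1, #included + 1)`.  Single-site Gibbs updates of
#' `(a_j, I_j)` (with `a_j` integrated out of the indicator draw), joint
#' updates of the variances, `pi` and the intercept.  Reported effects are
#' posterior means of `a_j I_j`, matching the predictive use
#' `yhat = mu + X g`.
#'
#' @param X raw dosage matrix (columns are centred internally).
#' @param y phenotype vector.
#' @param chain a [chain_settings()].
#' @param pi_fixed keep `pi` at this value instead of sampling it
#'   (`NULL` = estimate; [bayes_c()] passes 0.90).
#' @param pi_init starting value of `pi`, default 0.5.
#' @param nu prior degrees of freedom of both scaled inverse-chi-square
#'   priors, default 4.2.
#' @param genetic_share prior guess of the fraction of phenotypic variance
#'   captured by markers, used to set the prior scales, default 0.5.
#' @param fix_sigma_a,fix_sigma_e freeze a variance at the given value
#'   (used for ridge-limit checks), default `NULL` = sample.
#' @return A [marker_effects()]; `extra` carries `pi_mean` (posterior mean
#'   of pi), `prop_included` (posterior mean of `1 - pi`), traces of
#'   `sigma2_a`, `sigma2_e`, `pi`, `n_included`, the posterior-mean model
#'   size, and batch-mean Monte-Carlo standard errors `mcse_g`.
#' @export
bayes_cpi <- function(X, y, chain = chain_settings(), pi_fixed = NULL,
                      pi_init = 0.5, nu = 4.2, genetic_share = 0.5,
                      fix_sigma_a = NULL, fix_sigma_e = NULL) {
  stop_unless(inherits(chain, "chain_settings"), "chain must be chain_settings")
  p_freq <- col_allele_freq(X)
  stop_unless(any(p_freq > 0 & p_freq < 1), "all markers monomorphic")
  with_seed(chain$seed,
            bayes_cpi_impl(X, y, chain, pi_fixed, pi_init, nu, genetic_share,
                           fix_sigma_a, fix_sigma_e, p_freq))
}

bayes_cpi_impl <- function(X, y, chain, pi_fixed, pi_init, nu, genetic_share,
                           fix_sigma_a, fix_sigma_e, p_freq) {
  cd <- center_dosages(X, p_freq)
  Xc <- cd$Xc
  n <- nrow(Xc); p <- ncol(Xc)
  xtx <- colSums(Xc^2)
  vy <- stats::var(y)

  pi_cur <- pi_fixed %||% pi_init
  k_sum <- max(2 * sum(p_freq * (1 - p_freq)), 1e-8)
  # prior scales: mode of scaled-inv-chisq(nu, S) is nu S / (nu + 2)
  sa0 <- fix_sigma_a %||%
    (genetic_share * vy / (max(1 - pi_cur, 0.05) * k_sum))
  se0 <- fix_sigma_e %||% ((1 - genetic_share) * vy)
  Sa <- sa0 * (nu + 2) / nu
  Se <- se0 * (nu + 2) / nu

  sigma2_a <- sa0
  sigma2_e <- se0
  mu <- mean(y)
  g <- numeric(p)            # current a_j * I_j
  e <- y - mu

  n_keep <- chain$n_iter - chain$burn_in
  n_batch <- max(min(20L, n_keep %/% 10L), 1L)
  batch_of <- rep(seq_len(n_batch), length.out = n_keep)  # cyclic, fine for SEs
  g_sum <- numeric(p)
  g_batch <- matrix(0, p, n_batch)
  mu_sum <- 0
  kept <- 0L
  tr_len <- n_keep %/% chain$thin
  trace <- matrix(NA_real_, tr_len, 4,
                  dimnames = list(NULL, c("sigma2_a", "sigma2_e", "pi",
                                          "n_included")))
  ti <- 0L

  for (it in seq_len(chain$n_iter)) {
    # intercept
    mu_new <- stats::rnorm(1, mu + mean(e), sqrt(sigma2_e / n))
    e <- e - (mu_new - mu)
    mu <- mu_new

    log_odds_prior <- log(1 - pi_cur) - log(pi_cur)
    incl <- logical(p)
    for (j in seq_len(p)) {
      gj <- g[j]
      if (xtx[j] <= 0) next
      xj <- Xc[, j]
      rhs <- sum(xj * e) + xtx[j] * gj
      v0 <- xtx[j] * sigma2_e
      v1 <- v0 + xtx[j]^2 * sigma2_a
      llr <- 0.5 * (log(v0 / v1) + rhs^2 * (1 / v0 - 1 / v1))
      pr1 <- if (pi_cur <= 0) 1 else if (pi_cur >= 1) 0 else
        1 / (1 + exp(-(llr + log_odds_prior)))
      if (stats::runif(1) < pr1) {
        cj <- xtx[j] + sigma2_e / sigma2_a
        gnew <- stats::rnorm(1, rhs / cj, sqrt(sigma2_e / cj))
        incl[j] <- TRUE
      } else gnew <- 0
      if (gnew != gj) {
        e <- e - xj * (gnew - gj)
        g[j] <- gnew
      }
    }
    m_in <- sum(incl)

    if (is.null(fix_sigma_a))
      sigma2_a <- (nu * Sa + sum(g[incl]^2)) / stats::rchisq(1, nu + m_in)
    if (is.null(fix_sigma_e))
      sigma2_e <- (nu * Se + sum(e^2)) / stats::rchisq(1, nu + n)
    if (is.null(pi_fixed))
      pi_cur <- stats::rbeta(1, p - m_in + 1, m_in + 1)

    if (it > chain$burn_in) {
      kept <- kept + 1L
      g_sum <- g_sum + g
      g_batch[, batch_of[kept]] <- g_batch[, batch_of[kept]] + g
      mu_sum <- mu_sum + mu
      if (kept %% chain$thin == 0L) {
        ti <- ti + 1L
        trace[ti, ] <- c(sigma2_a, sigma2_e, pi_cur, m_in)
      }
    }
  }

  g_mean <- g_sum / kept
  batch_n <- tabulate(batch_of[seq_len(kept)], n_batch)
  bm <- sweep(g_batch, 2, pmax(batch_n, 1), "/")
  mcse_g <- sqrt(apply(bm, 1, stats::var) / n_batch)
  names(g_mean) <- colnames(X)

  marker_effects(mu = mu_sum / kept, g = g_mean, method = "bayes_cpi",
                 allele_freq = p_freq, center = cd$center,
                 extra = list(pi_mean = mean(trace[, "pi"]),
                              prop_included = 1 - mean(trace[, "pi"]),
                              mean_model_size = mean(trace[, "n_included"]),
                              sigma2_a_mean = mean(trace[, "sigma2_a"]),
                              sigma2_e_mean = mean(trace[, "sigma2_e"]),
                              trace = trace, mcse_g = mcse_g,
                              chain = chain))
}

#' BayesC marker effects (exclusion probability fixed)
#'
#' Identical to [bayes_cpi()] except that the exclusion probability `pi` is
#' kept fixed (default 0.90) rather than sampled.
#'
#' @inheritParams bayes_cpi
#' @param pi_fixed the fixed exclusion probability, default 0.90.
#' @return A [marker_effects()], method label `"bayes_c"`.
#' @export
bayes_c <- function(X, y, chain = chain_settings(), pi_fixed = 0.90, ...) {
  fit <- bayes_cpi(X, y, chain = chain, pi_fixed = pi_fixed, ...)
  fit$method <- "bayes_c"
  fit
}
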
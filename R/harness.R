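# Study harness: run every estimator on identical cross-validation
# partitions and collect predictions, timings and evaluation tables.

#' Settings for a benchmark run
#'
#' Desk-scale defaults; `chain` settings reproduce the long-chain preset
#' when passed `chain_settings(50000, 5000)`.
#'
#' @param chain [chain_settings()] for the Gibbs-sampled methods.
#' @param rf_trees,rf_mtry random-forest size; `rf_mtry = NULL` uses `p/3`.
#' @param svr_cost SVR regularisation parameter, default 1.
#' @param lasso_folds internal CV folds for the LASSO, default 10.
#' @param ss_by_alpha FDR level of the SS_BY scan, default 0.01.
#' @param ss_abs_sd_mult SS_ABS screening multiplier, default 1.5.
#' @param seed base seed for the stochastic methods.
#' @return list of class `benchmark_settings`.
#' @export
benchmark_settings <- function(chain = chain_settings(1500, 300),
                               rf_trees = 1000, rf_mtry = NULL, svr_cost = 1,
                               lasso_folds = 10, ss_by_alpha = 0.01,
                               ss_abs_sd_mult = 1.5, seed = 1L) {
  structure(list(chain = chain, rf_trees = rf_trees, rf_mtry = rf_mtry,
                 svr_cost = svr_cost, lasso_folds = lasso_folds,
                 ss_by_alpha = ss_by_alpha, ss_abs_sd_mult = ss_abs_sd_mult,
                 seed = as.integer(seed)),
            class = "benchmark_settings")
}

#' All supported estimator labels
#' @return character vector.
#' @export
benchmark_methods <- function() {
  c("rr_gblup", "ss_by", "ss_abs", "lasso", "em_bayes_b", "bayes_cpi",
    "bayes_c", "rkhs", "svr", "rf", "pol")
}

#' Run a set of genomic-prediction methods on shared CV partitions
#'
#' For every plan and method: train on the reference animals only, predict
#' the validation animals, record wall time.  The pedigree-only baseline
#' (`"pol"`) additionally requires the pedigree; its variance ratio comes
#' from `h2` as `lambda = (1 - h2) / h2`.
#'
#' @param geno a [genotype_matrix()] without missing values.
#' @param y named (adjusted) phenotype vector covering all plan animals.
#' @param plans list of plans from [make_cv_plans()].
#' @param methods subset of [benchmark_methods()].
#' @param h2 heritability of `y` used for the ridge variance ratio and the
#'   polygenic baseline.
#' @param pedigree pedigree data frame (required when `"pol"` is run).
#' @param settings a [benchmark_settings()].
#' @param keep_fits keep the marker-effect fits (memory!), default FALSE.
#' @return list of class `benchmark_run`: `predictions` (data frame
#'   `animal, y_obs, y_pred, method, strategy, replicate`), `timing`,
#'   `fits` (nested list or NULL), `h2`.
#' @export
run_benchmark <- function(geno, y, plans, methods = benchmark_methods(),
                          h2, pedigree = NULL, settings = benchmark_settings(),
                          keep_fits = FALSE) {
  stop_unless(all(methods %in% benchmark_methods()),
              "unknown method label(s)")
  X <- geno$dosages
  stop_unless(!anyNA(X), "impute genotypes before benchmarking")
  A <- NULL
  if ("pol" %in% methods) {
    stop_unless(!is.null(pedigree), "pol needs a pedigree")
    A <- a_matrix(pedigree)
  }
  preds <- list(); times <- list(); fits <- list()
  for (plan in plans) {
    Xr <- X[plan$ref_ids, , drop = FALSE]
    Xv <- X[plan$val_ids, , drop = FALSE]
    yr <- y[plan$ref_ids]
    yv <- y[plan$val_ids]
    spec <- ridge_spec_from_h2(max(min(h2, 0.99), 0.01), stats::var(yr),
                               col_allele_freq(Xr))
    for (m in methods) {
      t0 <- proc.time()[["elapsed"]]
      res <- fit_one_method(m, Xr, yr, Xv, spec, A, plan, settings)
      dt <- proc.time()[["elapsed"]] - t0
      key <- paste(m, plan$strategy, plan$replicate, sep = ".")
      preds[[key]] <- data.frame(animal = plan$val_ids, y_obs = unname(yv),
                                 y_pred = unname(res$predictions), method = m,
                                 strategy = plan$strategy,
                                 replicate = plan$replicate)
      times[[key]] <- data.frame(method = m, strategy = plan$strategy,
                                 replicate = plan$replicate, seconds = dt)
      if (keep_fits) fits[[key]] <- res$fit
    }
  }
  structure(list(predictions = do.call(rbind, c(preds, make.row.names = FALSE)),
                 timing = do.call(rbind, c(times, make.row.names = FALSE)),
                 fits = if (keep_fits) fits, h2 = h2),
            class = "benchmark_run")
}

fit_one_method <- function(m, Xr, yr, Xv, spec, A, plan, settings) {
  ch <- settings$chain
  seed_m <- settings$seed + plan$replicate
  switch(m,
    rr_gblup = {
      fit <- rr_gblup_svd(Xr, yr, spec = spec)
      list(predictions = predict(fit, Xv), fit = fit)
    },
    ss_by = {
      fit <- ss_by(Xr, yr, spec = spec, alpha = settings$ss_by_alpha)
      list(predictions = predict(fit, Xv), fit = fit)
    },
    ss_abs = {
      fit <- ss_abs(Xr, yr, spec = spec, sd_mult = settings$ss_abs_sd_mult)
      list(predictions = predict(fit, Xv), fit = fit)
    },
    lasso = {
      fit <- lasso_cv(Xr, yr, folds = settings$lasso_folds, seed = seed_m)
      list(predictions = predict(fit, Xv), fit = fit)
    },
    em_bayes_b = {
      fit <- em_bayes_b(Xr, yr)
      list(predictions = predict(fit, Xv), fit = fit)
    },
    bayes_cpi = {
      fit <- bayes_cpi(Xr, yr, chain = chain_settings(ch$n_iter, ch$burn_in,
                                                      ch$thin, seed_m))
      list(predictions = predict(fit, Xv), fit = fit)
    },
    bayes_c = {
      fit <- bayes_c(Xr, yr, chain = chain_settings(ch$n_iter, ch$burn_in,
                                                    ch$thin, seed_m))
      list(predictions = predict(fit, Xv), fit = fit)
    },
    rkhs = {
      kern <- gaussian_kernel(Xr, Xv)
      fit <- rkhs_gibbs(kern, yr, chain = chain_settings(ch$n_iter,
                                                         ch$burn_in, ch$thin,
                                                         seed_m))
      list(predictions = fit$predictions, fit = fit)
    },
    svr = {
      fit <- svr_fit(Xr, yr, Xv, cost = settings$svr_cost)
      list(predictions = fit$predictions, fit = NULL)
    },
    rf = {
      fit <- rf_fit(Xr, yr, Xv, n_trees = settings$rf_trees,
                    mtry = settings$rf_mtry %||% max(floor(ncol(Xr) / 3), 1),
                    seed = seed_m)
      list(predictions = fit$predictions, fit = NULL)
    },
    pol = {
      lambda <- spec$sigma2_e / spec$sigma2_u
      fit <- polygenic_blup(yr, A, plan$ref_ids, plan$val_ids, lambda)
      list(predictions = fit$predictions, fit = NULL)
    })
}

#' Evaluation table of a benchmark run
#'
#' One [evaluate_predictions()] row per (method, strategy, replicate).
#'
#' @param run a `benchmark_run`.
#' @param h2 heritability for the accuracy column, default the run's.
#' @return data frame with the evaluation statistics per cell.
#' @export
summarize_benchmark <- function(run, h2 = run$h2) {
  cells <- split(run$predictions,
                 interaction(run$predictions$method,
                             run$predictions$strategy,
                             run$predictions$replicate, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(cell) {
    ev <- evaluate_predictions(cell$y_obs, cell$y_pred, h2 = h2)
    cbind(data.frame(method = cell$method[1], strategy = cell$strategy[1],
                     replicate = cell$replicate[1]), ev)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-replicate means and standard errors of an evaluation table
#'
#' @param report output of [summarize_benchmark()].
#' @return data frame with per (method, strategy) means and SEs of every
#'   statistic.
#' @export
aggregate_benchmark <- function(report) {
  stats_cols <- c("predictive_ability", "bias", "inflation", "nrmse",
                  "accuracy")
  cells <- split(report, interaction(report$method, report$strategy,
                                     drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(cell) {
    row <- data.frame(method = cell$method[1], strategy = cell$strategy[1],
                      n_replicates = nrow(cell))
    for (s in stats_cols) {
      v <- cell[[s]]
      row[[paste0(s, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(s, "_se")]] <- stats::sd(v, na.rm = TRUE) /
        sqrt(sum(!is.na(v)))
    }
    row
  }))
  rownames(out) <- NULL
  out
}
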
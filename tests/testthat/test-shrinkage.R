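# Ridge solvers, subset selection and the LASSO.

test_that("direct, SVD and GSRU ridge solutions agree on random systems", {
  for (seed in 1:3) {
    X <- random_dosages(20, 50, seed = seed)
    set.seed(seed + 100)
    y <- rnorm(20)
    lam <- c(0.5, 5, 80)[seed]
    f_dir <- rr_gblup_direct(X, y, lambda = lam)
    f_svd <- rr_gblup_svd(X, y, lambda = lam)
    f_gsru <- gsru_solve(X, y, lambda = lam, tol = 1e-11)
    expect_lt(max(abs(f_dir$g - f_svd$g)), 1e-8)
    expect_lt(max(abs(f_svd$g - f_gsru$g)), 1e-6)
  }
})

test_that("huge shrinkage collapses effects onto the intercept", {
  X <- random_dosages(30, 40, seed = 5)
  y <- rnorm(30) + X[, 1]
  f <- rr_gblup_svd(X, y, lambda = 1e12)
  expect_lt(sqrt(sum(f$g^2)), 1e-6)
  expect_equal(predict(f, X), rep(mean(y), 30), tolerance = 1e-4)
})

test_that("ridge spec computes k and lambda as defined", {
  sp <- ridge_spec(sigma2_u = 2, sigma2_e = 1, allele_freq = rep(0.5, 40))
  expect_equal(sp$k, 20)  # 2 * sum(0.25) = p/2
  expect_equal(sp$lambda, 1 / (2 / 20))
  expect_error(ridge_spec(0, 1, k = 10), "positive")
})

test_that("ridge predictions are invariant to marker permutation", {
  X <- random_dosages(25, 30, seed = 7)
  set.seed(7); y <- rnorm(25)
  perm <- sample(ncol(X))
  f1 <- rr_gblup_svd(X, y, lambda = 3)
  f2 <- rr_gblup_svd(X[, perm], y, lambda = 3)
  expect_equal(predict(f1, X), predict(f2, X[, perm]), tolerance = 1e-9)
})

test_that("GSRU handles degenerate markers and matches the one-step form", {
  X <- cbind(m1 = c(2, 0, 1, 1, 2, 0), m2 = rep(1, 6))  # m2 has no variance
  set.seed(1); y <- rnorm(6)
  f <- gsru_solve(X, y, lambda = 2, tol = 1e-12)
  expect_equal(unname(f$g["m2"]), 0)

  # single marker, one sweep from a zero start: g = x'y / (x'x + lambda)
  x1 <- X[, 1, drop = FALSE]
  f1 <- suppressWarnings(gsru_solve(x1, y, lambda = 2, max_iter = 1,
                                    tol = 0))
  xc <- x1[, 1] - mean(x1[, 1]); yc <- y - mean(y)
  expect_equal(unname(f1$g), sum(xc * yc) / (sum(xc^2) + 2),
               tolerance = 1e-12)
})

test_that("SS_BY single-marker scan adjusts p-values by the BY step-up rule", {
  pop <- tiny_pop()
  qc <- qc_filter(pop$genotypes)
  X <- qc$dosages
  y <- pop$phenotypes$sparse
  spec <- ridge_spec_from_h2(0.5, var(y), col_allele_freq(X))
  fit <- ss_by(X, y, spec, alpha = 0.01)
  # independent step-up oracle with the harmonic-sum factor
  p <- fit$extra$p_raw
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  stepped <- rev(cummin(rev(pmin(m * cm * p[ord] / seq_len(m), 1))))
  oracle <- numeric(m); oracle[ord] <- stepped
  expect_equal(unname(fit$extra$p_adjusted), oracle, tolerance = 1e-12)
  expect_identical(unname(fit$selected),
                   unname(fit$extra$p_adjusted <= 0.01 & p < 1))
  # selected markers were refit jointly: effects exist only on the subset
  expect_true(all(fit$g[!fit$selected] == 0))
})

test_that("SS_BY with one test leaves the p-value unadjusted, and flags empty scans", {
  x1 <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1), ncol = 1,
               dimnames = list(NULL, "m1"))
  set.seed(3); y <- rnorm(8)
  spec <- ridge_spec(1, 1, allele_freq = 0.4)
  f <- ss_by(x1, y, spec, alpha = 0.5)
  expect_equal(f$extra$p_adjusted, f$extra$p_raw, tolerance = 1e-12)

  f_empty <- ss_by(x1, y, spec, alpha = 1e-12)
  expect_true(f_empty$extra$empty_selection)
  expect_equal(predict(f_empty, x1), rep(mean(y), 8))
})

test_that("SS_ABS selects the upper variance tail and degenerates sensibly", {
  X <- random_dosages(80, 60, seed = 11)
  set.seed(11)
  y <- 1.5 * (X[, 7] - mean(X[, 7])) + rnorm(80, 0, 0.4)
  spec <- ridge_spec_from_h2(0.5, var(y), col_allele_freq(X))
  f <- ss_abs(X, y, spec)
  expect_true(f$selected[7])
  expect_lt(sum(f$selected), 8)  # one huge-effect locus among nulls

  # sd_mult -> infinity selects nothing; -> -infinity selects everything,
  # and the refit then equals the one-stage ridge on all markers
  f_none <- ss_abs(X, y, spec, sd_mult = 1e9)
  expect_true(f_none$extra$empty_selection)
  f_all <- ss_abs(X, y, spec, sd_mult = -1e9)
  expect_true(all(f_all$selected))
  expect_equal(f_all$g, rr_gblup_svd(X, y, spec = spec)$g,
               tolerance = 1e-9)
})

test_that("SS_ABS concentrates selection near true QTL under LD", {
  hits <- 0; tot <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_families = 25, family_size_mean = 10,
                      n_markers = 300, n_extra_loci = 80,
                      n_generations = 12, genome_length_morgans = 0.6,
                      trait_architectures = list(
                        trait_architecture("t", n_qtl = 10,
                                           qtl_variance_fraction = 0.6,
                                           largest_qtl_fraction = 0.2,
                                           h2 = 0.6)),
                      seed = s)
    pop <- simulate_population(cfg)
    X <- pop$genotypes$dosages
    y <- pop$phenotypes$t
    spec <- ridge_spec_from_h2(0.6, var(y), col_allele_freq(X))
    f <- ss_abs(X, y, spec)
    sel_pos <- pop$genotypes$positions[f$selected]
    qtl_pos <- pop$qtl$position
    if (length(sel_pos)) {
      near <- vapply(sel_pos,
                     function(p) min(abs(p - qtl_pos)) <= 0.01, logical(1))
      hits <- hits + sum(near); tot <- tot + length(near)
    }
  }
  expect_gt(hits / tot, 0.5)  # most selected loci within 1 cM of a QTL
})

test_that("LASSO is sparse on few-QTL traits and its path fits monotonically", {
  X <- random_dosages(150, 250, seed = 13)
  set.seed(13)
  idx <- sample(250, 10)
  y <- drop(scale(X[, idx] %*% rnorm(10))) * sqrt(0.6) +
    rnorm(150, 0, sqrt(0.4))
  f <- lasso_cv(X, y, seed = 99)
  expect_lt(f$extra$n_nonzero, 100)  # far fewer than p
  expect_gt(f$extra$n_nonzero, 0)
  # training MSE is non-increasing as the penalty decreases along the path
  path <- f$extra$cvfit$glmnet.fit
  mse <- colMeans((y - predict(path, X))^2)
  expect_true(all(diff(mse) < 1e-8))
  # reproducible fold assignment
  f2 <- lasso_cv(X, y, seed = 99)
  expect_identical(f$g, f2$g)
})
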
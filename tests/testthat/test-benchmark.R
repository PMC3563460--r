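# CV designs, evaluation statistics, method comparison, expected accuracy,
# Ne estimation, genetic groups and effect-distribution summaries.

test_that("cross-validation plans respect family structure and reproduce", {
  pop <- tiny_pop()
  ph <- pop$phenotypes
  fam <- setNames(pop$pedigree$family[match(ph$animal, pop$pedigree$animal)],
                  ph$animal)
  w <- make_cv_plans(fam, "within-family", n_replicates = 4, seed = 3)
  for (pl in w) {
    expect_setequal(c(pl$ref_ids, pl$val_ids), names(fam))
    both <- table(fam[pl$ref_ids])
    # every family of size >= 2 appears on both sides
    big <- names(which(table(fam) >= 2))
    expect_true(all(big %in% names(table(fam[pl$ref_ids]))))
    expect_true(all(big %in% names(table(fam[pl$val_ids]))))
  }
  a <- make_cv_plans(fam, "across-family", n_replicates = 4, seed = 3)
  for (pl in a) {
    expect_equal(length(intersect(unique(fam[pl$ref_ids]),
                                  unique(fam[pl$val_ids]))), 0)
    expect_lt(abs(length(pl$ref_ids) / length(fam) - 0.55), 0.08)
  }
  expect_identical(make_cv_plans(fam, "within-family", 4, seed = 3), w)
  expect_false(identical(make_cv_plans(fam, "within-family", 4, seed = 4),
                         w))
})

test_that("reference sets hit the target fraction within family granularity", {
  set.seed(10)
  fam1000 <- setNames(rep(sprintf("F%02d", 1:91), rpois(91, 10) + 1),
                      NULL)
  fam1000 <- fam1000[1:min(length(fam1000), 1000)]
  names(fam1000) <- sprintf("A%04d", seq_along(fam1000))
  n <- length(fam1000)
  for (pl in make_cv_plans(fam1000, "across-family", 5, seed = 1)) {
    expect_gte(length(pl$ref_ids), round(0.52 * n))
    expect_lte(length(pl$ref_ids), round(0.58 * n))
  }
})

test_that("evaluation statistics match closed forms and handle zero-SD predictions", {
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  ev <- evaluate_predictions(y, y, h2 = 0.5)
  expect_equal(ev$predictive_ability, 1)
  expect_equal(ev$bias, 0)
  expect_equal(ev$inflation, 1)
  expect_equal(ev$nrmse, 0)
  expect_equal(ev$accuracy, 1 / sqrt(0.5))

  ev2 <- evaluate_predictions(y, y / 2)
  expect_equal(ev2$predictive_ability, 1)
  expect_equal(ev2$inflation, 2)  # regression of y on y/2

  ev3 <- evaluate_predictions(y, rep(0.4, 5))
  expect_true(is.na(ev3$predictive_ability))
  expect_true(is.na(ev3$inflation))
  expect_equal(ev3$bias, mean(0.4 - y) / sd(y))
  expect_equal(ev3$nrmse, sqrt(mean((0.4 - y)^2)) / diff(range(y)))

  # hand-computed oracle on an arbitrary 5-point instance
  yh <- c(0.9, -0.2, 0.1, 1.4, -0.8)
  ev4 <- evaluate_predictions(y, yh, phenotypic_sd = 1.5)
  expect_equal(ev4$bias, sum(yh - y) / 5 / 1.5)
  expect_equal(ev4$inflation,
               cor_by_hand(y, yh) * sd(y) / sd(yh), tolerance = 1e-10)
  expect_equal(ev4$predictive_ability, cor_by_hand(y, yh),
               tolerance = 1e-12)
})

test_that("paired method comparison flags only real differences", {
  rep_df <- data.frame(
    method = rep(c("a", "b", "c"), each = 6),
    replicate = rep(1:6, 3),
    predictive_ability = c(0.50, 0.52, 0.48, 0.51, 0.49, 0.50,
                           0.50, 0.52, 0.48, 0.51, 0.49, 0.50,   # b == a
                           0.20, 0.22, 0.18, 0.21, 0.19, 0.20))  # far below
  cmp <- compare_methods(rep_df)
  p_ab <- cmp$pairs[cmp$pairs$method1 == "a" & cmp$pairs$method2 == "b", ]
  expect_true(p_ab$degenerate)     # identical per-replicate values
  expect_false(isTRUE(p_ab$significant))
  p_ac <- cmp$pairs[cmp$pairs$method1 == "a" & cmp$pairs$method2 == "c", ]
  expect_true(p_ac$significant)
  expect_equal(cmp$letters[["a"]], cmp$letters[["b"]])
  expect_false(cmp$letters[["a"]] == cmp$letters[["c"]])

  # constant nonzero difference: zero variance of differences, degenerate
  rep2 <- data.frame(method = rep(c("x", "y"), each = 3), replicate = rep(1:3, 2),
                     predictive_ability = c(0.5, 0.6, 0.7, 0.4, 0.5, 0.6))
  cmp2 <- compare_methods(rep2)
  expect_true(cmp2$pairs$degenerate[1])
  expect_equal(cmp2$pairs$p_raw[1], 0)
})

test_that("expected accuracy follows the deterministic formula and its limits", {
  # N h2 = Me gives exactly 1/sqrt(2)
  ea <- expected_accuracy(N = 2800 / 0.5, h2 = 0.5, Ne = 100, L = 14,
                          me_mode = "Me2")
  expect_equal(ea$Me, 2800)
  expect_equal(ea$accuracy, 1 / sqrt(2), tolerance = 1e-12)
  # vanishing reference size drives accuracy to zero
  expect_lt(expected_accuracy(N = 1e-6, h2 = 0.5, Ne = 100, L = 14,
                              me_mode = "Me1")$accuracy, 1e-3)
  # the two segment-number approximations
  e1 <- expected_accuracy(1000, 0.5, 100, 14, "Me1")
  expect_equal(e1$Me, 2 * 100 * 14 / log(4 * 100 * 14), tolerance = 1e-12)
  e2 <- expected_accuracy(1000, 0.5, 100, 14, "Me2")
  expect_equal(e2$accuracy, sqrt(500 / 3300), tolerance = 1e-12)
  expect_error(expected_accuracy(-1, 0.5, 100, 14), "positive")
})

test_that("Ne is recovered within a factor of two and unlinked markers are flagged", {
  ratios <- numeric(0)
  for (s in 1:2) {
    cfg <- sim_config(n_families = 50, family_size_mean = 10,
                      n_markers = 400, n_extra_loci = 50,
                      founder_corr_morgans = 0.005, pop_size = 150,
                      n_generations = 40, seed = 60 + s)
    pop <- simulate_population(cfg)
    est <- estimate_ne_from_ld(qc_filter(pop$genotypes), seed = s)
    expect_true(est$informative)
    ratios <- c(ratios, est$Ne / 150)
  }
  expect_true(all(ratios > 0.5 & ratios < 2))

  # no linkage: r2 flat in distance
  X <- random_dosages(300, 120, seed = 63)
  g <- genotype_matrix(X, positions = sort(runif(120)))
  expect_warning(est0 <- estimate_ne_from_ld(g), "uninformative")
  expect_false(est0$informative)
})

test_that("genetic groups recover separable subpopulations", {
  set.seed(65)
  # two subpopulations with strongly diverged allele frequencies
  p1 <- runif(120, 0.05, 0.35); p2 <- runif(120, 0.65, 0.95)
  X <- rbind(t(replicate(40, rbinom(120, 2, p1))),
             t(replicate(40, rbinom(120, 2, p2))))
  rownames(X) <- sprintf("i%02d", 1:80)
  gg <- genetic_groups(X, k_max = 6)
  expect_equal(gg$k, 2)
  truth <- rep(1:2, each = 40)
  tab <- table(gg$labels, truth)
  expect_equal(sum(apply(tab, 1, max)) / 80, 1)  # perfect up to labels

  # k-means refinement does not worsen the within-cluster sum of squares
  wss <- function(lab) {
    sum(vapply(unique(lab), function(g2) {
      sub <- gg$embedding[lab == g2, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  expect_lte(wss(gg$labels), wss(gg$ward_labels) + 1e-9)
})

test_that("group tests match the weighted Fisher-z statistic and its edge cases", {
  gs_equal <- data.frame(replicate = 1, group = 1:3, r = 0.4, n = 30)
  gt <- group_tests(gs_equal)
  expect_equal(gt$per_replicate$statistic, 0)
  expect_equal(gt$mean_p, 1)
  expect_equal(atanh(0), 0)  # Fisher transform fixed point at r = 0

  gs <- data.frame(replicate = 1, group = 1:3,
                   r = c(0.6, 0.3, 0.45), n = c(40, 25, 32))
  gt2 <- group_tests(gs)
  z <- atanh(gs$r); w <- gs$n - 3
  zb <- sum(w * z) / sum(w)
  stat <- sum(w * (z - zb)^2)
  expect_equal(gt2$per_replicate$statistic, stat, tolerance = 1e-12)
  expect_equal(gt2$per_replicate$p, pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # small groups are excluded and logged
  gs3 <- rbind(gs, data.frame(replicate = 1, group = 4, r = 0.9, n = 3))
  gt3 <- group_tests(gs3)
  expect_equal(nrow(gt3$excluded), 1)
  expect_equal(gt3$per_replicate$statistic, stat, tolerance = 1e-12)

  # phenotypic variance homogeneity via Fligner-Killeen
  set.seed(66)
  phe <- c(rnorm(50, 0, 1), rnorm(50, 0, 3))
  grp <- rep(1:2, each = 50)
  gt4 <- group_tests(gs, phenotypes = phe, groups = grp)
  expect_lt(gt4$fligner_p, 0.01)
})

test_that("effect-distribution summaries rank per-locus variance correctly", {
  g <- rep(0.2, 200)
  fit <- marker_effects(mu = 0, g = g, method = "toy",
                        allele_freq = rep(0.5, 200))
  s <- effect_distribution_summary(fit, x_list = c(20, 100))
  expect_equal(unname(s$t_x["t20"]), 0.1)   # uniform: top 10% hold 10%
  expect_equal(unname(s$t_x["t100"]), 0.5)
  expect_equal(s$n_nonzero, 200)

  g2 <- c(rep(0, 99), 3)
  fit2 <- marker_effects(0, g2, "toy", allele_freq = rep(0.3, 100))
  s2 <- effect_distribution_summary(fit2, x_list = c(1, 20))
  expect_equal(unname(s2$t_x), c(1, 1))
  expect_equal(s2$n_nonzero, 1)

  set.seed(67)
  g3 <- rnorm(10000)
  fit3 <- marker_effects(0, g3, "toy", allele_freq = rep(0.4, 10000))
  s3 <- effect_distribution_summary(fit3)
  expect_lt(abs(s3$excess_kurtosis), 0.2)  # normal effects
})

test_that("the harness serves identical partitions to every method", {
  pop <- tiny_pop()
  ph <- pop$phenotypes
  fam <- setNames(pop$pedigree$family[match(ph$animal, pop$pedigree$animal)],
                  ph$animal)
  plans <- make_cv_plans(fam, "within-family", n_replicates = 2, seed = 5)
  y <- setNames(ph$sparse, ph$animal)
  run <- run_benchmark(pop$genotypes, y, plans,
                       methods = c("rr_gblup", "lasso"), h2 = 0.5)
  by_method <- split(run$predictions, run$predictions$method)
  for (r in 1:2) {
    a1 <- sort(by_method$rr_gblup$animal[by_method$rr_gblup$replicate == r])
    a2 <- sort(by_method$lasso$animal[by_method$lasso$replicate == r])
    expect_identical(a1, a2)
  }
  s <- summarize_benchmark(run)
  expect_equal(nrow(s), 4)
  agg <- aggregate_benchmark(s)
  expect_equal(nrow(agg), 2)
  expect_true(all(is.finite(agg$predictive_ability_mean)))
})
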
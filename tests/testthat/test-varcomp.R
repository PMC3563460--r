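# Relationship matrix, EM-REML, phenotype adjustment and polygenic BLUP.

test_that("a_matrix reproduces textbook relationships", {
  ped <- data.frame(animal = c("a", "b", "c"), sire = NA, dam = NA)
  expect_equal(unname(a_matrix(ped)), diag(3))

  ped2 <- data.frame(animal = c("s", "d", "o1", "o2"),
                     sire = c(NA, NA, "s", "s"),
                     dam = c(NA, NA, "d", "d"))
  A <- a_matrix(ped2)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["o1", "s"], 0.5)
  expect_equal(diag(A), c(s = 1, d = 1, o1 = 1, o2 = 1))
})

test_that("a_matrix matches a gene-dropping estimate on a 3-generation pedigree", {
  ped <- data.frame(animal = c("f1", "f2", "f3", "p1", "p2", "x"),
                    sire = c(NA, NA, NA, "f1", "f1", "p1"),
                    dam = c(NA, NA, NA, "f2", "f3", "p2"))
  A <- a_matrix(ped)
  # drop two distinct founder alleles per founder through the pedigree and
  # estimate relationship as twice the coancestry (allele-matching rate)
  set.seed(1)
  nrep <- 1e5
  founder_alleles <- function(id) cbind(paste0(id, "a"), paste0(id, "b"))
  drop_one <- function() {
    al <- list(f1 = c("f1a", "f1b"), f2 = c("f2a", "f2b"),
               f3 = c("f3a", "f3b"))
    al$p1 <- c(sample(al$f1, 1), sample(al$f2, 1))
    al$p2 <- c(sample(al$f1, 1), sample(al$f3, 1))
    al$x <- c(sample(al$p1, 1), sample(al$p2, 1))
    al
  }
  pairs <- list(c("p1", "p2"), c("x", "p1"), c("x", "f1"))
  counts <- matrix(0, nrep, length(pairs))
  for (r in seq_len(nrep)) {
    al <- drop_one()
    for (k in seq_along(pairs)) {
      i <- al[[pairs[[k]][1]]]; j <- al[[pairs[[k]][2]]]
      counts[r, k] <- mean(outer(i, j, "=="))
    }
  }
  est <- 2 * colMeans(counts)
  for (k in seq_along(pairs)) {
    expect_equal(est[k], A[pairs[[k]][1], pairs[[k]][2]], tolerance = 0.01)
  }
})

test_that("pedigree cycles are rejected", {
  bad <- data.frame(animal = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(a_matrix(bad), "cycle")
})

test_that("EM-REML finds a boundary for pure noise and scales equivariantly", {
  pop <- tiny_pop()
  ph0 <- pop$phenotypes
  A0 <- a_matrix(pop$pedigree)[ph0$animal, ph0$animal]
  set.seed(4)
  y <- rnorm(nrow(ph0))  # no family resemblance at all
  fit <- suppressWarnings(reml_animal_model(y, A0, se = FALSE, tol = 1e-6))
  expect_lt(fit$h2, 0.25)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))

  ph <- pop$phenotypes
  A <- a_matrix(pop$pedigree)[ph$animal, ph$animal]
  f1 <- reml_animal_model(ph$sparse, A, cage = ph$cage, se = FALSE,
                          tol = 1e-6)
  f2 <- reml_animal_model(2 * ph$sparse, A, cage = ph$cage, se = FALSE,
                          tol = 1e-6)
  expect_equal(f2$sigma2_u / f1$sigma2_u, 4, tolerance = 0.05)
  expect_equal(f2$h2, f1$h2, tolerance = 0.01)
  expect_true(all(diff(f1$loglik_trace) > -1e-6))
})

test_that("phenotype adjustment removes cage variance and is idempotent", {
  pop <- tiny_pop()
  ph <- pop$phenotypes
  A <- a_matrix(pop$pedigree)[ph$animal, ph$animal]
  fit <- reml_animal_model(ph$cagey, A, cage = ph$cage, se = FALSE,
                           tol = 1e-6)
  adj <- adjust_phenotypes(fit)
  expect_lt(var(adj), var(ph$cagey))
  expect_equal(mean(adj), 0, tolerance = 1e-10)
  expect_true(attr(adj, "adjusted"))
  # adjusting the adjusted phenotypes changes little: cage BLUPs refit on
  # adj are near zero
  fit2 <- reml_animal_model(adj, A, cage = ph$cage, se = FALSE, tol = 1e-6)
  adj2 <- adjust_phenotypes(fit2)
  expect_equal(as.numeric(adj2), as.numeric(adj), tolerance = 0.1)

  # single cage, intercept only: adjustment is mean-centring
  fitc <- suppressWarnings(
    reml_animal_model(ph$sparse[1:50], A[1:50, 1:50], se = FALSE,
                      tol = 1e-6))
  expect_equal(as.numeric(adjust_phenotypes(fitc)),
               as.numeric(ph$sparse[1:50] - mean(ph$sparse[1:50])),
               tolerance = 1e-8)
})

test_that("polygenic BLUP equals a dense GLS oracle and zeroes disconnected animals", {
  ped <- data.frame(animal = c("s", "d", "o1", "o2", "o3", "u1", "u2"),
                    sire = c(NA, NA, "s", "s", "s", NA, NA),
                    dam = c(NA, NA, "d", "d", "d", NA, "u1"))
  A <- a_matrix(ped)
  set.seed(2)
  yr <- setNames(rnorm(3, 1), c("o1", "o2", "o3"))
  lambda <- 2
  res <- polygenic_blup(yr, A, ref_ids = names(yr),
                        val_ids = c("u2", "s"), lambda = lambda)
  # oracle: u_hat = sigma2_u A Z' V^-1 (y - X beta_gls), V on the REF block
  s2u <- 1; s2e <- lambda
  Ar <- A[names(yr), names(yr)]
  V <- s2u * Ar + s2e * diag(3)
  X <- matrix(1, 3, 1)
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% yr)
  u_all <- s2u * A[, names(yr)] %*% solve(V, yr - X %*% beta)
  expect_equal(res$ebv, drop(u_all)[names(res$ebv)], tolerance = 1e-8)
  expect_equal(res$mu, as.numeric(beta), tolerance = 1e-8)
  # pedigree-disconnected validation animals predict exactly zero
  expect_equal(unname(res$predictions["u2"]), 0)
  # mixed-model equations are satisfied
  mme <- res$mme
  expect_lt(max(abs(mme$C %*% mme$solution - mme$rhs)), 1e-8)
  # infinite shrinkage drives every EBV to zero
  res0 <- polygenic_blup(yr, A, names(yr), "u2", lambda = 1e10)
  expect_lt(max(abs(res0$ebv)), 1e-6)
})

test_that("recovered heritability ordering matches the simulated ordering", {
  # three traits with well-separated h2 in a small population
  archs <- list(
    trait_architecture("lo", n_qtl = 5, qtl_variance_fraction = 0.1,
                       h2 = 0.1),
    trait_architecture("mid", n_qtl = 5, qtl_variance_fraction = 0.4,
                       h2 = 0.45),
    trait_architecture("hi", n_qtl = 5, qtl_variance_fraction = 0.7,
                       h2 = 0.8))
  cfg <- sim_config(n_families = 40, family_size_mean = 10, n_markers = 60,
                    n_extra_loci = 40, n_generations = 8,
                    trait_architectures = archs, seed = 31)
  pop <- simulate_population(cfg)
  ph <- pop$phenotypes
  A <- a_matrix(pop$pedigree)[ph$animal, ph$animal]
  h2s <- vapply(c("lo", "mid", "hi"), function(tr) {
    suppressWarnings(reml_animal_model(ph[[tr]], A, se = FALSE,
                                       tol = 1e-6))$h2
  }, numeric(1))
  expect_true(h2s["lo"] < h2s["mid"] && h2s["mid"] < h2s["hi"])
})
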
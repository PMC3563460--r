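# Population simulator, marker QC, LD summary and imputation.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_families = 6, n_markers = 60, n_extra_loci = 40,
                    n_generations = 5, seed = 9)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$pedigree, p2$pedigree)
})

test_that("final generation reproduces the target full-sib family structure", {
  cfg <- sim_config(n_families = 168, family_size_mean = 11, n_markers = 40,
                    n_extra_loci = 30, n_generations = 3, seed = 2)
  pop <- simulate_population(cfg)
  fam <- pop$pedigree$family[!is.na(pop$pedigree$family)]
  expect_equal(length(unique(fam)), 168)
  expect_equal(mean(table(fam)), 11, tolerance = 0.05)
  off <- pop$pedigree[!is.na(pop$pedigree$family), ]
  # full sibs: one sire and one dam per family
  expect_true(all(tapply(off$sire, off$family,
                         function(s) length(unique(s))) == 1))
})

test_that("trait construction matches the requested architecture", {
  pop <- tiny_pop()
  ph <- pop$phenotypes
  expect_equal(var(ph$tbv_sparse) / var(ph$sparse), 0.5, tolerance = 1e-6)
  expect_equal(var(ph$cagey), 1, tolerance = 1e-6)
  arch0 <- trait_architecture("null", n_qtl = 0, qtl_variance_fraction = 0,
                              h2 = 0)
  cfg0 <- sim_config(n_families = 8, n_markers = 50, n_extra_loci = 20,
                     n_generations = 4, trait_architectures = list(arch0),
                     seed = 5)
  pop0 <- simulate_population(cfg0)
  expect_equal(sd(pop0$phenotypes$tbv_null), 0)
  expect_equal(var(pop0$phenotypes$null), 1, tolerance = 1e-6)
})

test_that("realized heritability tracks the target at moderate size", {
  cfg <- sim_config(n_families = 91, family_size_mean = 11, n_markers = 80,
                    n_extra_loci = 60, n_generations = 10,
                    trait_architectures = list(
                      trait_architecture("t", n_qtl = 10,
                                         qtl_variance_fraction = 0.4,
                                         h2 = 0.5)),
                    seed = 7)
  pop <- simulate_population(cfg)
  h2_real <- var(pop$phenotypes$tbv_t) / var(pop$phenotypes$t)
  expect_gt(h2_real, 0.4)
  expect_lt(h2_real, 0.6)
})

test_that("infeasible architectures are rejected with a diagnostic", {
  expect_error(trait_architecture("bad", 5, 0.6, h2 = 0.5), "exceed")
  expect_error(trait_architecture("bad", 5, 0.3, largest_qtl_fraction = 0.4,
                                  h2 = 0.5), "largest")
  expect_error(trait_architecture("bad", 5, 0.5, h2 = 0.6,
                                  cage_variance_fraction = 0.5), "exceed 1")
})

test_that("adjacent_r2 agrees with hand-computed correlations", {
  dos <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 2, 1, 1, 0), c(2, 2, 0, 1, 0, 1))
  g <- genotype_matrix(dos)
  got <- adjacent_r2(g)
  exp_r2 <- mean(c(cor_by_hand(dos[, 1], dos[, 2])^2,
                   cor_by_hand(dos[, 2], dos[, 3])^2))
  expect_equal(got$mean_r2, exp_r2, tolerance = 1e-12)
  expect_equal(got$n_pairs, 2)

  dup <- genotype_matrix(cbind(dos[, 1], dos[, 1]))
  expect_equal(adjacent_r2(dup)$mean_r2, 1)

  mono <- genotype_matrix(cbind(rep(1, 6), rep(2, 6), rep(0, 6)))
  res <- adjacent_r2(mono)
  expect_true(is.na(res$mean_r2))
  expect_equal(res$n_skipped, 2)
})

test_that("independent markers show near-zero adjacent r2", {
  X <- random_dosages(800, 30, seed = 3)
  expect_lt(adjacent_r2(genotype_matrix(X))$mean_r2, 0.02)
})

test_that("more random-mating generations do not increase adjacent LD", {
  r2_at <- function(gens, seed) {
    cfg <- sim_config(n_families = 10, n_markers = 120, n_extra_loci = 30,
                      n_generations = gens, seed = seed)
    adjacent_r2(simulate_population(cfg)$genotypes)$mean_r2
  }
  for (s in 1:2) expect_gte(r2_at(3, s), r2_at(40, s) - 0.03)
})

test_that("qc_filter removes low-MAF and HWE-failing markers with a log", {
  # columns: healthy HWE, monomorphic, exact HWE counts, total heterozygote deficit
  hwe_ok <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  deficit <- c(rep(0, 50), rep(2, 50))
  rare <- c(rep(0, 98), 1, 1)
  g <- genotype_matrix(cbind(ok = hwe_ok, mono = rep(2, 100),
                             hw = hwe_ok, bad = deficit, rare = rare))
  out <- qc_filter(g, maf_min = 0.05, hwe_alpha = 1e-4)
  excl <- attr(out, "exclusions")
  expect_setequal(colnames(out$dosages), c("ok", "hw"))
  expect_equal(excl$reason[excl$marker == "mono"], "maf")
  expect_equal(excl$reason[excl$marker == "rare"], "maf")
  expect_equal(excl$reason[excl$marker == "bad"], "hwe")
  # complete heterozygote deficit: chi-square equals n, p-value tiny
  expect_lt(excl$value[excl$marker == "bad"],
            pchisq(99, 1, lower.tail = FALSE))
})

test_that("qc_filter is idempotent", {
  qc1 <- qc_filter(tiny_pop()$genotypes)
  qc2 <- qc_filter(qc1)
  expect_identical(qc1$dosages, qc2$dosages)
  expect_equal(nrow(attr(qc2, "exclusions")), 0)
})

test_that("impute_ppca recovers structure and never touches observed cells", {
  g0 <- tiny_pop()$genotypes
  expect_identical(impute_ppca(g0)$dosages, g0$dosages)  # nothing missing

  # rank-1 matrix with one deleted cell is recovered exactly
  u <- c(0, 1, 2, 1, 0, 2, 2, 1)
  r1 <- outer(u, c(1, 1, 1, 1, 1))
  r1na <- r1; r1na[3, 2] <- NA
  imp <- impute_ppca(genotype_matrix(r1na), rank = 1, tol = 1e-10)
  expect_lt(abs(imp$dosages[3, 2] - r1[3, 2]), 1e-6)

  # on an LD-structured matrix, beats column-mean imputation on the same mask
  dos <- g0$dosages[1:60, 1:100]
  set.seed(8)
  mask <- cbind(sample(nrow(dos), 25, TRUE), sample(ncol(dos), 25, TRUE))
  mask <- mask[!duplicated(mask), ]
  truth <- dos[mask]
  holey <- dos; holey[mask] <- NA
  imp2 <- impute_ppca(genotype_matrix(holey), rank = 10)
  obs <- !is.na(holey)
  expect_equal(imp2$dosages[obs], as.numeric(dos[obs]))
  cm <- colMeans(holey, na.rm = TRUE)
  err_pca <- mean(abs(imp2$dosages[mask] - truth))
  err_cm <- mean(abs(cm[mask[, 2]] - truth))
  expect_lt(err_pca, err_cm)
  expect_true(all(imp2$dosages >= 0 & imp2$dosages <= 2))
})

test_that("genotype and table round-trips preserve data", {
  g <- tiny_pop()$genotypes
  f <- tempfile(fileext = ".tsv")
  write_genotypes(g, f)
  g2 <- read_genotypes(f)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$positions, g$positions, tolerance = 1e-12)
  ped <- tiny_pop()$pedigree
  fp <- tempfile(fileext = ".csv")
  write_table_csv(ped, fp)
  expect_equal(read_table_csv(fp)$animal, ped$animal)
})
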
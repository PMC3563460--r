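# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small LD-structured population with a sparse and a dense trait.
tiny_pop <- function() {
  if (is.null(.fixtures$tiny_pop)) {
    .fixtures$tiny_pop <- simulate_population(sim_config(
      n_families = 14, family_size_mean = 9, n_markers = 180,
      n_extra_loci = 120, n_generations = 15, genome_length_morgans = 0.5,
      trait_architectures = list(
        trait_architecture("sparse", n_qtl = 8, qtl_variance_fraction = 0.5,
                           largest_qtl_fraction = 0.15, h2 = 0.5),
        trait_architecture("cagey", n_qtl = 5, qtl_variance_fraction = 0.3,
                           h2 = 0.4, cage_variance_fraction = 0.3)),
      seed = 42))
  }
  .fixtures$tiny_pop
}

# iid dosage matrix (no LD), handy for estimator algebra checks
random_dosages <- function(n, p, maf = 0.3, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  matrix(rbinom(n * p, 2, maf), n, p,
         dimnames = list(NULL, sprintf("m%03d", seq_len(p))))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Pearson correlation from first principles (independent of stats::cor)
cor_by_hand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}
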
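# Canonical desk-scale study conditions: the synthetic population and the
# trait pair (sparse vs dense genetic architecture) on which the method
# comparison is run.

#' Trait pair contrasting sparse and dense genetic architectures
#'
#' A 10-QTL trait with all of its genetic variance on the mapped QTL, and
#' a 600-QTL trait of the same heritability: the contrast under which
#' variable-selection methods are expected to gain over uniform shrinkage
#' on the sparse trait while uniform shrinkage stays competitive on the
#' dense one.
#'
#' @param h2 heritability of both traits, default 0.5.
#' @return list of two [trait_architecture()] objects named `sparse10`
#'   and `dense600`.
#' @export
contrast_architectures <- function(h2 = 0.5) {
  list(trait_architecture("sparse10", n_qtl = 10, qtl_variance_fraction = h2,
                          largest_qtl_fraction = 0.12, h2 = h2),
       trait_architecture("dense600", n_qtl = 600,
                          qtl_variance_fraction = h2, h2 = h2))
}

#' Canonical benchmark population configuration
#'
#' The desk-scale population on which the method comparison is run:
#' about 1,000 phenotyped animals in 91 full-sib families of mean size 11,
#' 2,000 panel markers on a 2-Morgan genome (adjacent-marker r-squared
#' around 0.5), 8 founder lines, 50 generations of random mating, and the
#' sparse/dense trait contrast of [contrast_architectures()].
#'
#' @param seed RNG seed.
#' @param n_markers panel size, default 2000.
#' @param n_families full-sib family count, default 91.
#' @return A [sim_config()].
#' @export
benchmark_config <- function(seed, n_markers = 2000, n_families = 91) {
  sim_config(n_families = n_families, family_size_mean = 11,
             n_markers = n_markers, n_extra_loci = 650,
             genome_length_morgans = 2,
             trait_architectures = contrast_architectures(), seed = seed)
}

#' Run the method comparison under the canonical study conditions
#'
#' Simulates the [benchmark_config()] population for one seed, builds one
#' within-family and one across-family split, runs all methods on the
#' sparse trait under both splits, and the shrinkage-versus-selection
#' trio (RR-GBLUP, LASSO, emBayesB) on the dense trait under the
#' within-family split.
#'
#' @param seed seed for the population and the splits.
#' @param settings a [benchmark_settings()].
#' @param methods methods run on the sparse trait.
#' @return list with `sparse` and `dense` evaluation tables (one
#'   [summarize_benchmark()] row per method and strategy), `pol_sd_across`
#'   (SD of the polygenic predictions on the across-family split) and
#'   `population`.
#' @export
run_contrast_study <- function(seed,
                               settings = benchmark_settings(
                                 chain = chain_settings(400, 100, seed = seed),
                                 rf_trees = 300),
                               methods = benchmark_methods()) {
  pop <- simulate_population(benchmark_config(seed))
  ph <- pop$phenotypes
  fam <- stats::setNames(pop$pedigree$family[match(ph$animal,
                                                   pop$pedigree$animal)],
                         ph$animal)
  plans <- c(make_cv_plans(fam, "within-family", n_replicates = 1,
                           seed = seed),
             make_cv_plans(fam, "across-family", n_replicates = 1,
                           seed = seed))
  y_sparse <- stats::setNames(ph$sparse10, ph$animal)
  run_sp <- run_benchmark(pop$genotypes, y_sparse, plans, methods = methods,
                          h2 = 0.5, pedigree = pop$pedigree,
                          settings = settings)
  pol_across <- run_sp$predictions[run_sp$predictions$method == "pol" &
                                     run_sp$predictions$strategy ==
                                       "across-family", ]
  y_dense <- stats::setNames(ph$dense600, ph$animal)
  run_de <- run_benchmark(pop$genotypes, y_dense, plans[1],
                          methods = intersect(methods,
                                              c("rr_gblup", "lasso",
                                                "em_bayes_b")),
                          h2 = 0.5, settings = settings)
  list(sparse = summarize_benchmark(run_sp),
       dense = summarize_benchmark(run_de),
       pol_sd_across = if (nrow(pol_across)) stats::sd(pol_across$y_pred)
       else NA_real_,
       population = pop)
}

#' Demonstration population for the analysis workflow
#'
#' A mid-sized population carrying the five default trait architectures
#' (sparse immunological traits through a low-heritability conformation
#' trait), used by the numbered analysis scripts: 60 full-sib families of
#' mean size 11, 1,200 panel markers, cage effects nested in families.
#'
#' @param seed RNG seed, default 2024.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 2024) {
  sim_config(n_families = 60, family_size_mean = 11, n_markers = 1200,
             n_extra_loci = 300, seed = seed)
}
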
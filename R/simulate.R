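# Gene-dropping simulator for an admixed multi-founder population with
# full-sib family structure, shared-cage effects and configurable trait
# architectures.

# One meiosis: recombine a parent's two haplotypes (0/1 vectors over loci at
# `pos` Morgans) under the Haldane model (Poisson crossovers, no
# interference).
recombine <- function(hap1, hap2, pos, length_morgans) {
  n_xo <- stats::rpois(1, length_morgans)
  start <- sample.int(2L, 1L) - 1L
  if (n_xo == 0L) {
    if (start == 0L) return(hap1) else return(hap2)
  }
  points <- sort(stats::runif(n_xo, 0, length_morgans))
  phase <- (findInterval(pos, points) + start) %% 2L
  ifelse(phase == 0L, hap1, hap2)
}

# Advance a population one generation of random mating: each offspring has
# two distinct random parents, one recombinant gamete from each.
next_generation <- function(h1, h2, n_off, pos, length_morgans) {
  n_par <- nrow(h1)
  o1 <- matrix(0L, n_off, ncol(h1))
  o2 <- matrix(0L, n_off, ncol(h1))
  for (i in seq_len(n_off)) {
    par <- sample.int(n_par, 2L)
    o1[i, ] <- recombine(h1[par[1L], ], h2[par[1L], ], pos, length_morgans)
    o2[i, ] <- recombine(h1[par[2L], ], h2[par[2L], ], pos, length_morgans)
  }
  list(h1 = o1, h2 = o2)
}

#' Simulate a heterogeneous-stock-like population
#'
#' Founder haplotypes are drawn once per inbred line (each line fixed for a
#' random allele at every locus), mixed in equal proportions into a base
#' population, gene-dropped through `n_generations` of random mating with
#' Haldane-model recombination, and finally organised into full-sib families
#' produced by monogamous pairs drawn from the last random-mating
#' generation.  Phenotypes are built per trait architecture as
#' `y = QTL effects + polygenic background + cage effect + residual`,
#' with each variance component empirically rescaled so realized fractions
#' match the architecture (total phenotypic variance 1).  True breeding
#' values are retained for validation.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_population`: a list with elements
#'   `genotypes` ([genotype_matrix()] of the phenotyped generation at panel
#'   markers), `pedigree` (data frame `animal, sire, dam, family`; family
#'   parents are founders with unknown parents), `phenotypes` (data frame
#'   with `animal`, `cage`, one column per trait and matching `tbv_<trait>`
#'   truth columns), `qtl` (data frame of causal loci per trait with
#'   positions and effects) and `config`.
#' @examples
#' pop <- simulate_population(sim_config(n_families = 10, n_markers = 120,
#'                                       n_generations = 10, seed = 7))
#' pop$genotypes
#' @export
simulate_population <- function(config) {
  stop_unless(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  L <- config$genome_length_morgans
  n_loci <- config$n_markers + config$n_extra_loci
  pos <- sort(stats::runif(n_loci, 0, L))

  # founder inbred lines: fixed haplotype per line with along-genome
  # autocorrelation (latent AR(1) thresholded at per-locus ancestral
  # frequencies), mimicking the shared descent of real inbred founders and
  # providing the high short-range LD of a multi-founder mosaic
  theta <- stats::runif(n_loci, 0.2, 0.8)
  rho <- exp(-diff(pos) / config$founder_corr_morgans)
  lines <- matrix(0L, config$n_founder_lines, n_loci)
  for (l in seq_len(config$n_founder_lines)) {
    z <- numeric(n_loci)
    z[1] <- stats::rnorm(1)
    eps <- stats::rnorm(n_loci - 1L)
    for (k in 2:n_loci) z[k] <- rho[k - 1L] * z[k - 1L] +
        sqrt(1 - rho[k - 1L]^2) * eps[k - 1L]
    lines[l, ] <- as.integer(z < stats::qnorm(theta))
  }

  # base population: two line haplotypes per individual, lines equally likely
  n_pop <- config$pop_size
  h1 <- lines[sample.int(config$n_founder_lines, n_pop, replace = TRUE), , drop = FALSE]
  h2 <- lines[sample.int(config$n_founder_lines, n_pop, replace = TRUE), , drop = FALSE]

  for (g in seq_len(config$n_generations)) {
    off <- next_generation(h1, h2, n_pop, pos, L)
    h1 <- off$h1; h2 <- off$h2
  }

  # full-sib families from monogamous pairs of distinct final-generation parents
  n_fam <- config$n_families
  par_idx <- sample.int(n_pop, 2L * n_fam)
  sires <- par_idx[seq_len(n_fam)]
  dams <- par_idx[n_fam + seq_len(n_fam)]
  fam_sizes <- 1L + stats::rpois(n_fam, max(config$family_size_mean - 1, 0))
  n_off <- sum(fam_sizes)

  o1 <- matrix(0L, n_off, n_loci)
  o2 <- matrix(0L, n_off, n_loci)
  fam_of <- integer(n_off)
  k <- 0L
  for (f in seq_len(n_fam)) {
    for (j in seq_len(fam_sizes[f])) {
      k <- k + 1L
      o1[k, ] <- recombine(h1[sires[f], ], h2[sires[f], ], pos, L)
      o2[k, ] <- recombine(h1[dams[f], ], h2[dams[f], ], pos, L)
      fam_of[k] <- f
    }
  }
  dos_all <- o1 + o2  # n_off x n_loci

  # split loci into observed panel and causal pool
  if (config$mask_qtl) {
    pool <- sort(sample.int(n_loci, config$n_extra_loci))
    panel <- setdiff(seq_len(n_loci), pool)
  } else {
    panel <- sort(sample.int(n_loci, config$n_markers))
    pool <- setdiff(seq_len(n_loci), panel)
  }

  fam_ids <- sprintf("F%03d", seq_len(n_fam))
  animal_ids <- sprintf("A%04d", seq_len(n_off))
  sire_ids <- sprintf("S%03d", seq_len(n_fam))
  dam_ids <- sprintf("D%03d", seq_len(n_fam))
  pedigree <- rbind(
    data.frame(animal = sire_ids, sire = NA_character_, dam = NA_character_,
               family = NA_character_),
    data.frame(animal = dam_ids, sire = NA_character_, dam = NA_character_,
               family = NA_character_),
    data.frame(animal = animal_ids, sire = sire_ids[fam_of],
               dam = dam_ids[fam_of], family = fam_ids[fam_of]))

  # cages: nested within family (cages of ~cage_size animals, never mixing
  # families, so cage is confounded with family between families but
  # separable within), or random groups ignoring family
  cage <- if (config$cage_assignment == "family-confounded") {
    unlist(lapply(seq_len(n_fam), function(f) {
      sz <- fam_sizes[f]
      n_cg <- max(1L, ceiling(sz / config$cage_size))
      sprintf("F%03d.K%d", f, rep_len(seq_len(n_cg), sz))
    }), use.names = FALSE)
  } else {
    n_cg <- max(1L, ceiling(n_off / config$cage_size))
    sprintf("C%04d", sample(rep_len(seq_len(n_cg), n_off)))
  }

  phen <- data.frame(animal = animal_ids, cage = cage)
  qtl_records <- list()
  for (arch in config$trait_architectures) {
    parts <- simulate_trait(arch, dos_all, pool, pos, cage)
    phen[[arch$name]] <- parts$y
    phen[[paste0("tbv_", arch$name)]] <- parts$tbv
    qtl_records[[arch$name]] <- parts$qtl
  }
  qtl <- do.call(rbind, qtl_records)
  rownames(qtl) <- NULL

  geno <- dos_all[, panel, drop = FALSE]
  rownames(geno) <- animal_ids
  colnames(geno) <- sprintf("M%05d", panel)

  structure(list(genotypes = genotype_matrix(geno, positions = pos[panel]),
                 pedigree = pedigree, phenotypes = phen, qtl = qtl,
                 config = config),
            class = "sim_population")
}

# Build one trait: mapped QTL (first QTL carries the `largest` share),
# polygenic background over the remaining pool loci, cage effect, residual.
simulate_trait <- function(arch, dos_all, pool, pos, cage) {
  n <- nrow(dos_all)
  qtl_df <- data.frame(trait = character(), locus = integer(),
                       position = numeric(), effect = numeric())
  qtl_part <- rep(0, n); bg_part <- rep(0, n)
  if (arch$n_qtl > 0 && arch$qtl_variance_fraction > 0) {
    qtl_idx <- sample(pool, arch$n_qtl)
    eff <- stats::rnorm(arch$n_qtl)
    large <- scale_to_var(dos_all[, qtl_idx[1L]] * eff[1L],
                          arch$largest_qtl_fraction)
    rest <- if (arch$n_qtl > 1L) {
      scale_to_var(dos_all[, qtl_idx[-1L], drop = FALSE] %*% eff[-1L],
                   max(arch$qtl_variance_fraction - arch$largest_qtl_fraction, 0))
    } else rep(0, n)
    qtl_part <- scale_to_var(large + rest, arch$qtl_variance_fraction)
    qtl_df <- data.frame(trait = arch$name, locus = qtl_idx,
                         position = pos[qtl_idx], effect = eff)
  }
  bg_frac <- arch$h2 - arch$qtl_variance_fraction
  bg_idx <- setdiff(pool, qtl_df$locus)
  if (bg_frac > 1e-12 && length(bg_idx) > 0) {
    bg_part <- scale_to_var(dos_all[, bg_idx, drop = FALSE] %*%
                              stats::rnorm(length(bg_idx)), bg_frac)
  }
  tbv <- scale_to_var(qtl_part + bg_part, arch$h2)
  # cage effects are orthogonalised against the cage means of the breeding
  # values (at the cage level, so they stay constant within cage) and the
  # residual against both, so the realized variance fractions are exact
  cage_part <- rep(0, n)
  if (arch$cage_variance_fraction > 0) {
    cage_f <- factor(cage)
    cage_eff <- stats::rnorm(nlevels(cage_f))
    tbv_mean <- tapply(tbv, cage_f, mean)
    n_c <- as.numeric(table(cage_f))
    w_fit <- stats::lm.wfit(cbind(1, tbv_mean), cage_eff, w = n_c)
    cage_part <- scale_to_var(w_fit$residuals[as.integer(cage_f)],
                              arch$cage_variance_fraction)
  }
  resid_frac <- 1 - arch$h2 - arch$cage_variance_fraction
  e <- stats::rnorm(n)
  e <- scale_to_var(stats::lm.fit(cbind(1, tbv, cage_part), e)$residuals,
                    resid_frac)
  list(y = as.numeric(tbv + cage_part + e), tbv = as.numeric(tbv), qtl = qtl_df)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d animals, %d markers, %d families, traits: %s\n",
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              length(unique(stats::na.omit(x$pedigree$family))),
              paste(vapply(x$config$trait_architectures, `[[`, "", "name"),
                    collapse = ", ")))
  invisible(x)
}
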
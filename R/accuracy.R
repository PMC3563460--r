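# Expected accuracy of genomic prediction from population parameters, and
# effective population size from the decay of linkage disequilibrium.

#' Expected accuracy of genomic breeding values
#'
#' Deterministic expectation `r = sqrt(N h2 / (N h2 + Me))`, where `N` is
#' the reference-set size, `h2` the (pseudo)heritability of the phenotypes
#' used for training and `Me` the number of independent chromosome
#' segments, approximated either as `Me1 = 2 Ne L / ln(4 Ne L)` or as
#' `Me2 = 2 Ne L` (`Ne` effective population size, `L` genome length in
#' Morgans).
#'
#' @param N reference-set size.
#' @param h2 heritability in (0, 1].
#' @param Ne effective population size.
#' @param L genome length in Morgans.
#' @param me_mode `"Me1"` (`2NeL/ln(4NeL)`) or `"Me2"` (`2NeL`).
#' @return list with `accuracy` and `Me`.
#' @examples
#' expected_accuracy(N = 1000, h2 = 0.5, Ne = 100, L = 14, me_mode = "Me2")
#' @export
expected_accuracy <- function(N, h2, Ne, L, me_mode = c("Me1", "Me2")) {
  me_mode <- match.arg(me_mode)
  stop_unless(N > 0 && h2 > 0 && Ne > 0 && L > 0, "all inputs must be positive")
  Me <- if (me_mode == "Me1") 2 * Ne * L / log(4 * Ne * L) else 2 * Ne * L
  list(accuracy = sqrt(N * h2 / (N * h2 + Me)), Me = Me)
}

#' Effective population size from linkage-disequilibrium decay
#'
#' Bins pairwise marker `r^2` by map distance `c` (Morgans) and fits the
#' Sved relation with sample-size correction,
#' `E[r^2] = 1 / (1 + 4 Ne c) + 1/n`, by nonlinear least squares on the
#' bin means (grid-refined fallback when the fit fails).  When `r^2` does
#' not decrease with distance the fit is flagged uninformative.
#'
#' @param geno a [genotype_matrix()] with map positions and no missing
#'   values.
#' @param n_bins number of distance bins, default 20.
#' @param max_markers cap on markers used (random subset), default 400.
#' @param max_dist largest pair distance used, default one quarter of the
#'   map length.
#' @param seed seed for the marker subsample.
#' @return list with `Ne`, `bins` (data frame `c`, `r2`, `n_pairs`),
#'   `informative` (logical).
#' @export
estimate_ne_from_ld <- function(geno, n_bins = 20, max_markers = 400,
                                max_dist = NULL, seed = 1L) {
  stop_unless(!is.null(geno$positions), "map positions required")
  stop_unless(!anyNA(geno$dosages), "complete genotypes required")
  pos <- geno$positions
  m <- geno$dosages
  n <- nrow(m)
  if (ncol(m) > max_markers) {
    keep <- with_seed(seed, sort(sample.int(ncol(m), max_markers)))
    m <- m[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  poly <- apply(m, 2, stats::sd) > 0
  m <- m[, poly, drop = FALSE]; pos <- pos[poly]
  max_dist <- max_dist %||% (diff(range(pos)) / 4)
  cc <- stats::cor(m)^2
  dd <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(dd)
  use <- ut & dd <= max_dist & dd > 0
  stop_unless(sum(use) > n_bins, "too few marker pairs")
  br <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dd[use], br, include.lowest = TRUE)
  r2bar <- tapply(cc[use], bin, mean)
  cmid <- (br[-1] + br[-length(br)]) / 2
  ok <- !is.na(r2bar)
  stop_unless(sum(ok) >= 2, "fewer than two informative distance bins")
  bins <- data.frame(c = cmid[ok], r2 = as.numeric(r2bar[ok]),
                     n_pairs = as.numeric(table(bin)[ok]))
  decay <- summary(stats::lm(r2 ~ c, data = bins))$coefficients
  informative <- decay["c", "Estimate"] < 0 && decay["c", "Pr(>|t|)"] < 0.05
  # moment start: invert the Sved relation at each bin, take the median
  r2a <- pmax(bins$r2 - 1 / n, 1e-6)
  ne0 <- stats::median((1 / r2a - 1) / (4 * bins$c))
  fit <- tryCatch(
    stats::nls(r2 ~ 1 / (1 + 4 * Ne * c) + 1 / n, data = bins,
               start = list(Ne = max(ne0, 1)), weights = bins$n_pairs),
    error = function(e) NULL)
  Ne <- if (!is.null(fit)) stats::coef(fit)[["Ne"]] else {
    grid <- exp(seq(log(1), log(1e5), length.out = 400))
    sse <- vapply(grid, function(ne)
      sum(bins$n_pairs * (bins$r2 - 1 / (1 + 4 * ne * bins$c) - 1 / n)^2),
      numeric(1))
    grid[which.min(sse)]
  }
  if (!informative)
    warning("r2 does not decay with distance; Ne estimate uninformative")
  list(Ne = Ne, bins = bins, informative = informative)
}
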
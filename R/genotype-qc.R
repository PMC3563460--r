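# Marker QC, linkage-disequilibrium summary and low-rank imputation.

#' Mean squared correlation between adjacent markers
#'
#' Markers are taken in map order; for every adjacent pair the squared
#' Pearson correlation of the dosage vectors is computed.  Pairs involving a
#' monomorphic marker have no defined correlation and are skipped (counted).
#'
#' @param geno a [genotype_matrix()] with no missing values and >= 2 markers.
#' @return list with `mean_r2` (NA when every pair is monomorphic),
#'   `n_pairs` used and `n_skipped`.
#' @export
adjacent_r2 <- function(geno) {
  m <- geno$dosages
  stop_unless(ncol(m) >= 2, "need at least two markers")
  stop_unless(!anyNA(m), "adjacent_r2 requires complete genotypes")
  sds <- apply(m, 2, stats::sd)
  r2 <- rep(NA_real_, ncol(m) - 1L)
  for (j in seq_len(ncol(m) - 1L)) {
    if (sds[j] > 0 && sds[j + 1L] > 0)
      r2[j] <- stats::cor(m[, j], m[, j + 1L])^2
  }
  n_skipped <- sum(is.na(r2))
  list(mean_r2 = if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE),
       n_pairs = sum(!is.na(r2)), n_skipped = n_skipped)
}

#' Marker quality control: MAF and Hardy-Weinberg filters
#'
#' Removes markers whose minor-allele frequency (from non-missing dosages)
#' falls below `maf_min`, and markers failing a 1-df chi-square
#' goodness-of-fit test of Hardy-Weinberg genotype proportions at level
#' `hwe_alpha`.  Monomorphic markers fail the MAF filter.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency, default 0.05.
#' @param hwe_alpha significance level of the HWE test, default `1e-4`.
#' @return A [genotype_matrix()] restricted to the retained markers, with an
#'   `exclusions` attribute: data frame `marker, reason, value` listing every
#'   removed marker (`reason` is `"maf"` or `"hwe"`).
#' @export
qc_filter <- function(geno, maf_min = 0.05, hwe_alpha = 1e-4) {
  m <- geno$dosages
  p <- col_allele_freq(m)
  maf <- pmin(p, 1 - p)
  hwe_p <- apply(m, 2, hwe_pvalue)
  fail_maf <- maf < maf_min | is.nan(maf)
  fail_hwe <- !fail_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
  excl <- rbind(
    data.frame(marker = geno$markers[fail_maf],
               reason = rep("maf", sum(fail_maf)),
               value = unname(maf[fail_maf])),
    data.frame(marker = geno$markers[fail_hwe],
               reason = rep("hwe", sum(fail_hwe)),
               value = unname(hwe_p[fail_hwe])))
  rownames(excl) <- NULL
  keep <- !(fail_maf | fail_hwe)
  if (!any(keep)) warning("qc_filter removed every marker")
  out <- genotype_matrix(m[, keep, drop = FALSE],
                         positions = geno$positions[keep])
  attr(out, "exclusions") <- excl
  out
}

# 1-df chi-square goodness-of-fit p-value for Hardy-Weinberg proportions.
hwe_pvalue <- function(dos) {
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  if (n == 0) return(NA_real_)
  obs <- c(sum(dos == 0), sum(dos == 1), sum(dos == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(NA_real_)  # monomorphic: HWE test undefined
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Impute missing dosages by iterative low-rank (probabilistic-PCA style)
#' reconstruction
#'
#' Missing cells are initialised at column means, then the matrix is
#' repeatedly approximated by its best rank-`rank` reconstruction (SVD of
#' the column-centred matrix, an EM iteration for the probabilistic PCA
#' model with the noise floor at zero) and the missing cells are replaced by
#' the reconstruction, clamped to `[0, 2]`.  Observed cells are never
#' altered.
#'
#' @param geno a [genotype_matrix()] with missing entries.
#' @param rank reconstruction rank, default 10 (capped at `min(n, p) - 1`).
#' @param max_iter maximum EM iterations, default 100.
#' @param tol convergence threshold on the largest absolute change of an
#'   imputed cell, default `1e-4`.
#' @param max_missing refuse inputs with a larger missing fraction, default 0.1.
#' @return A complete [genotype_matrix()]; attribute `converged` is `FALSE`
#'   (with a warning) when `max_iter` was exhausted.
#' @export
impute_ppca <- function(geno, rank = 10, max_iter = 100, tol = 1e-4,
                        max_missing = 0.1) {
  m <- geno$dosages
  miss <- is.na(m)
  frac <- mean(miss)
  stop_unless(frac <= max_missing,
              "missing fraction %.3f exceeds cap %.3f", frac, max_missing)
  if (!any(miss)) {
    out <- geno
    attr(out, "converged") <- TRUE
    return(out)
  }
  rank <- min(rank, min(dim(m)) - 1L)
  cm <- colMeans(m, na.rm = TRUE)
  filled <- m
  filled[miss] <- cm[col(m)[miss]]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(filled)
    sv <- svd(sweep(filled, 2, mu), nu = rank, nv = rank)
    recon <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
    recon <- sweep(recon, 2, mu, `+`)
    newvals <- pmin(pmax(recon[miss], 0), 2)
    delta <- max(abs(newvals - filled[miss]))
    filled[miss] <- newvals
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("impute_ppca did not converge in %d iterations", max_iter))
  out <- genotype_matrix(filled, positions = geno$positions)
  attr(out, "converged") <- converged
  out
}
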
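# Pedigree-only polygenic BLUP baseline (no marker information).

#' Polygenic BLUP predictions from pedigree and reference phenotypes
#'
#' Solves Henderson's mixed-model equations for `y = 1 mu + u + e`,
#' `u ~ N(0, sigma2_u A)`, using the phenotypes of the reference animals
#' only, and returns estimated breeding values; the prediction for a
#' validation animal is its EBV.  Validation animals with no pedigree link
#' to any reference animal get an EBV of exactly zero, so the standard
#' deviation of their predictions is zero and a correlation-based
#' predictive ability is undefined.
#'
#' @param y named phenotype vector (names are animal ids).
#' @param A numerator relationship matrix over all pedigree animals (with
#'   dimnames); must contain every reference and validation animal.
#' @param ref_ids,val_ids animal id vectors; reference phenotypes must be
#'   present in `y`.
#' @param lambda variance ratio `sigma2_e / sigma2_u` (from REML).
#' @return list with `ebv` (named, all animals in `A`), `predictions`
#'   (named, validation animals), `mu`.
#' @export
polygenic_blup <- function(y, A, ref_ids, val_ids, lambda) {
  ids <- rownames(A)
  stop_unless(!is.null(ids), "A needs animal ids as dimnames")
  stop_unless(all(val_ids %in% ids), "validation animals missing from pedigree")
  stop_unless(all(ref_ids %in% ids), "reference animals missing from pedigree")
  stop_unless(all(ref_ids %in% names(y)), "reference animals missing phenotypes")
  stop_unless(lambda > 0, "lambda must be positive")
  n_all <- length(ids)
  yr <- y[ref_ids]
  Z <- matrix(0, length(ref_ids), n_all)
  Z[cbind(seq_along(ref_ids), match(ref_ids, ids))] <- 1
  Ainv <- solve(A)
  nref <- length(ref_ids)
  # MME: [n, 1'Z; Z'1, Z'Z + lambda Ainv] [mu; u] = [1'y; Z'y]
  C <- rbind(cbind(nref, t(colSums(Z))),
             cbind(colSums(Z), crossprod(Z) + lambda * Ainv))
  rhs <- c(sum(yr), drop(crossprod(Z, yr)))
  sol <- solve(C, rhs)
  ebv <- sol[-1]
  names(ebv) <- ids
  list(ebv = ebv, predictions = ebv[val_ids], mu = unname(sol[1]),
       mme = list(C = C, rhs = rhs, solution = sol))
}
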
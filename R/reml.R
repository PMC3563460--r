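# EM-REML for the animal model with an optional random cage effect, and
# phenotype pre-adjustment.

#' EM-REML variance components for the animal model
#'
#' Fits `y = X b + u + c + e` with `u ~ N(0, sigma2_u A)`,
#' `c ~ N(0, sigma2_c I)` over cage levels and `e ~ N(0, sigma2_e I)`,
#' by expectation-maximisation REML expressed through the projection matrix
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`.  Each component update is
#'
#'   `sigma2_i <- sigma2_i + (sigma2_i^2 / q_i) (y' P B_i P y - tr(P B_i))`
#'
#' which leaves the restricted log-likelihood non-decreasing; an Aitken-type
#' extrapolation is attempted every few iterations and kept only when it
#' improves the likelihood, so monotonicity is preserved.
#'
#' @param y numeric response vector.
#' @param A numerator relationship matrix for the animals in `y` (same
#'   order); see [a_matrix()].
#' @param cage optional factor/character vector of cage labels (random
#'   effect); `NULL` drops the cage component.
#' @param X fixed-effect design matrix, default intercept only.
#' @param start optional starting values `c(u =, c =, e =)`; default splits
#'   `var(y)` equally across the fitted components.
#' @param tol relative restricted-log-likelihood convergence threshold.
#' @param max_iter maximum EM iterations.
#' @param accelerate apply guarded Aitken extrapolation, default `TRUE`.
#' @param se compute asymptotic standard errors from the expected
#'   information matrix, default `TRUE`.
#' @return Object of class `varcomp`: `sigma2_u`, `sigma2_c` (NA when no
#'   cage effect), `sigma2_e`, `h2 = sigma2_u / (sigma2_u + sigma2_c +
#'   sigma2_e)`, `se` (named vector), `loglik`, `loglik_trace`, `beta`
#'   (fixed effects), `cage_blup` (named), `ebv` (breeding values of the
#'   phenotyped animals), `converged`, `boundary`, `iterations`.
#' @export
reml_animal_model <- function(y, A, cage = NULL, X = NULL, start = NULL,
                              tol = 1e-7, max_iter = 300, accelerate = TRUE,
                              se = TRUE) {
  n <- length(y)
  A <- as.matrix(A)
  stop_unless(nrow(A) == n && ncol(A) == n, "A must be n x n for n = length(y)")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stop_unless(n >= ncol(X) + 2, "too few records for the fixed effects")
  has_cage <- !is.null(cage)
  if (has_cage) {
    cage <- factor(cage)
    stop_unless(length(cage) == n && !anyNA(cage),
                "every record needs a cage label")
    Zc <- stats::model.matrix(~ cage - 1)
    Cmat <- tcrossprod(Zc)
    q_c <- nlevels(cage)
  }
  vy <- stats::var(y)
  k <- if (has_cage) 3 else 2
  th <- start %||% rep(vy / k, k)  # order: u, (c,) e
  names(th) <- if (has_cage) c("u", "c", "e") else c("u", "e")
  floor_v <- 1e-8 * vy

  eval_step <- function(th) {
    V <- th["u"] * A + th["e"] * diag(n)
    if (has_cage) V <- V + th["c"] * Cmat
    cholV <- chol(V)
    Vi <- chol2inv(cholV)
    VX <- Vi %*% X
    XVX <- crossprod(X, VX)
    XVXi <- solve(XVX)
    P <- Vi - VX %*% XVXi %*% t(VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cholV))) +
                    determinant(XVX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    APy <- drop(A %*% Py)
    upd <- th
    upd["u"] <- th["u"] + th["u"]^2 / n * (sum(Py * APy) - sum(P * A))
    if (has_cage) {
      cs <- tapply(Py, cage, sum)
      upd["c"] <- th["c"] + th["c"]^2 / q_c * (sum(cs^2) - sum(P * Cmat))
    }
    upd["e"] <- th["e"] + th["e"]^2 / n * (sum(Py^2) - sum(diag(P)))
    list(ll = as.numeric(ll), upd = pmax(upd, floor_v), P = P, Py = Py,
         Vi = Vi, XVXi = XVXi, VX = VX)
  }

  ll_trace <- numeric(0)
  prev <- NULL
  hist <- list()
  converged <- FALSE
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- eval_step(th)
    ll_trace <- c(ll_trace, st$ll)
    if (!is.null(prev) && abs(st$ll - prev) / (abs(prev) + 1) < tol) {
      converged <- TRUE
      break
    }
    prev <- st$ll
    hist[[length(hist) + 1L]] <- th
    th_new <- st$upd
    # guarded SQUAREM-type extrapolation on the component sequence,
    # accepted only when it improves the restricted likelihood
    if (accelerate && length(hist) >= 2L && it %% 3L == 0L) {
      h <- length(hist)
      t0 <- hist[[h - 1L]]; t1 <- hist[[h]]; t2 <- th_new
      r <- t1 - t0
      v <- t2 - 2 * t1 + t0
      if (sum(v^2) > 1e-300) {
        alpha <- -sqrt(sum(r^2) / sum(v^2))
        ext <- pmax(t0 - 2 * alpha * r + alpha^2 * v, floor_v)
        ll_ext <- eval_step(ext)$ll
        if (is.finite(ll_ext) && ll_ext > st$ll) th_new <- ext
      }
    }
    th <- th_new
  }
  if (!converged)
    warning(sprintf("EM-REML did not converge in %d iterations", max_iter))

  sigma2_u <- th[["u"]]
  sigma2_c <- if (has_cage) th[["c"]] else NA_real_
  sigma2_e <- th[["e"]]
  total <- sigma2_u + (if (has_cage) sigma2_c else 0) + sigma2_e
  boundary <- th <= floor_v * 1.01

  ses <- NULL
  if (se) {
    PB <- list(u = st$P %*% A)
    if (has_cage) PB$c <- st$P %*% Cmat
    PB$e <- st$P
    kk <- length(PB)
    info <- matrix(0, kk, kk, dimnames = list(names(PB), names(PB)))
    for (i in seq_len(kk)) for (j in i:kk) {
      info[i, j] <- info[j, i] <- 0.5 * sum(PB[[i]] * t(PB[[j]]))
    }
    ses <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, kk))
    names(ses) <- names(PB)
  }

  beta <- drop(st$XVXi %*% crossprod(X, st$Vi %*% y))
  cage_blup <- if (has_cage) {
    cb <- sigma2_c * tapply(st$Py, cage, sum)
    cb[levels(cage)]
  } else NULL
  ebv <- sigma2_u * drop(A %*% st$Py)

  structure(list(sigma2_u = sigma2_u, sigma2_c = sigma2_c,
                 sigma2_e = sigma2_e, h2 = sigma2_u / total, se = ses,
                 loglik = st$ll, loglik_trace = ll_trace, beta = beta,
                 cage_blup = cage_blup, ebv = ebv, cage = cage, X = X, y = y,
                 converged = converged, boundary = boundary,
                 iterations = length(ll_trace)),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp> sigma2_u=%.4g sigma2_c=%.4g sigma2_e=%.4g h2=%.3f (%s, %d it)\n",
              x$sigma2_u, x$sigma2_c, x$sigma2_e, x$h2,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Pre-adjust phenotypes for fixed effects and the cage BLUP
#'
#' Subtracts the fitted fixed effects and the cage BLUP of a [reml_animal_model()]
#' fit from the raw phenotypes and mean-centres the result, mirroring
#' analyses in which marker-effect models are trained on pre-corrected
#' phenotypes rather than fitting environmental effects jointly.
#'
#' @param fit a `varcomp` object.
#' @param y phenotypes to adjust; defaults to the vector the model was
#'   fitted to.
#' @return Mean-centred adjusted phenotype vector with attribute
#'   `adjusted = TRUE`.
#' @export
adjust_phenotypes <- function(fit, y = fit$y) {
  stop_unless(inherits(fit, "varcomp"), "fit must come from reml_animal_model")
  adj <- y - drop(fit$X %*% fit$beta)
  if (!is.null(fit$cage_blup)) {
    stop_unless(!anyNA(fit$cage), "animal without cage record")
    adj <- adj - fit$cage_blup[as.character(fit$cage)]
  }
  adj <- as.numeric(adj - mean(adj))
  attr(adj, "adjusted") <- TRUE
  adj
}
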
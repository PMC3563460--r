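# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Stop unless a condition holds
#' @noRd
stop_unless <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Scale a numeric vector so its sample variance equals `target`
#'
#' Zero target or zero-variance input returns a zero vector of equal length.
#' @noRd
scale_to_var <- function(x, target) {
  x <- as.numeric(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0 || target <= 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(target / v)
}

#' Column-wise allele frequencies of allele 1 from dosages in {0,1,2}
#' @noRd
col_allele_freq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}
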
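# Numerator relationship matrix from a pedigree (tabular method).

#' Additive (numerator) relationship matrix
#'
#' Tabular-method computation of Wright's numerator relationship matrix.
#' Animals are processed in topological order (parents before offspring);
#' a pedigree containing a cycle is rejected.  Unknown parents are `NA`.
#'
#' @param pedigree data frame with columns `animal`, `sire`, `dam` (ids,
#'   `NA` for unknown parents).
#' @return Symmetric matrix with animal ids as dimnames; diagonal
#'   `1 + F_i` (inbreeding coefficient), so exactly 1 for non-inbred animals.
#' @examples
#' ped <- data.frame(animal = c("s", "d", "o1", "o2"),
#'                   sire = c(NA, NA, "s", "s"),
#'                   dam  = c(NA, NA, "d", "d"))
#' a_matrix(ped)["o1", "o2"]  # full sibs: 0.5
#' @export
a_matrix <- function(pedigree) {
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, , drop = FALSE]
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  stop_unless(all(is.na(ped$sire) | !is.na(si)) &&
                all(is.na(ped$dam) | !is.na(di)),
              "every named parent must appear as an animal")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (!is.na(s)) A[s, j] else 0) +
                      (if (!is.na(d)) A[d, j] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
  }
  # return in the caller's original animal order
  back <- match(pedigree$animal, id)
  A[back, back, drop = FALSE]
}

# Topological order of a pedigree; stops on cycles.
pedigree_order <- function(pedigree) {
  stop_unless(all(c("animal", "sire", "dam") %in% names(pedigree)),
              "pedigree needs columns animal, sire, dam")
  stop_unless(!anyDuplicated(pedigree$animal), "duplicated animal ids")
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$animal)
  di <- match(pedigree$dam, pedigree$animal)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  stop_unless(all(placed), "pedigree contains a cycle")
  ord
}
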
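# Cross-validation designs: within-family and across-family splits.

#' Replicated reference/validation splits respecting family structure
#'
#' Two strategies mirror the two prediction scenarios of interest in
#' family-structured populations: `"within-family"` splits every full-sib
#' family so that about `ref_fraction` of its members train the model (each
#' family keeps at least one animal on each side when its size permits),
#' while `"across-family"` packs whole families into the reference set
#' until it holds about `ref_fraction` of the animals, so that no family
#' spans both sets and validation animals are only distantly related to the
#' training data.  Identical plans are served to every method.
#'
#' @param families named vector mapping each phenotyped animal id to its
#'   full-sib family label.
#' @param strategy `"within-family"` or `"across-family"`.
#' @param n_replicates number of replicate splits, default 10.
#' @param ref_fraction target reference-set fraction, default 0.55.
#' @param seed RNG seed; a fixed seed reproduces the plans exactly.
#' @return list of `cv_plan` objects with `strategy`, `replicate`,
#'   `ref_ids`, `val_ids`, `ref_fraction`.
#' @export
make_cv_plans <- function(families, strategy = c("within-family", "across-family"),
                          n_replicates = 10, ref_fraction = 0.55, seed = 1L) {
  strategy <- match.arg(strategy)
  stop_unless(!is.null(names(families)), "families must be named by animal id")
  stop_unless(ref_fraction > 0 && ref_fraction < 1,
              "ref_fraction must be in (0, 1)")
  ids <- names(families)
  n <- length(ids)
  fam_split <- split(ids, families)
  if (strategy == "across-family") {
    target <- ref_fraction * n
    stop_unless(max(lengths(fam_split)) <= target,
                "a family is larger than the reference-set target")
  }
  with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    ref <- if (strategy == "within-family") {
      unlist(lapply(fam_split, function(members) {
        sz <- length(members)
        n_ref <- round(ref_fraction * sz)
        if (sz >= 2) n_ref <- min(max(n_ref, 1L), sz - 1L)
        sample(members, n_ref)
      }), use.names = FALSE)
    } else {
      target <- ref_fraction * n
      ord <- sample(names(fam_split))
      sizes <- cumsum(lengths(fam_split)[ord])
      n_fam <- which(sizes >= target)[1]
      # keep the last family only if it brings the count closer to target
      if (n_fam > 1 &&
          abs(sizes[n_fam - 1] - target) <= abs(sizes[n_fam] - target))
        n_fam <- n_fam - 1
      unlist(fam_split[ord[seq_len(n_fam)]], use.names = FALSE)
    }
    structure(list(strategy = strategy, replicate = r, ref_ids = ref,
                   val_ids = setdiff(ids, ref),
                   ref_fraction = ref_fraction),
              class = "cv_plan")
  }))
}
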
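# Genotype container and plain-text I/O.

#' Construct a genotype matrix object
#'
#' Dosage-coded genotypes (copies of allele 1, `0/1/2`, `NA` for missing)
#' for `n` animals at `p` ordered markers, with per-marker map positions and
#' allele frequencies recomputed from the non-missing dosages.
#'
#' @param dosages numeric `n x p` matrix with entries in `[0, 2]` or `NA`
#'   (raw genotypes are 0/1/2; imputed dosages may be fractional);
#'   rownames are animal ids, colnames marker ids (generated when absent).
#' @param positions optional numeric vector of marker positions in Morgans,
#'   non-decreasing.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `positions`, `allele_freq`, `animals`, `markers`.
#' @export
genotype_matrix <- function(dosages, positions = NULL) {
  dosages <- as.matrix(dosages)
  stop_unless(all(is.na(dosages) | (dosages >= 0 & dosages <= 2)),
              "dosages must lie in [0, 2] or be NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("A%04d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("M%05d", seq_len(ncol(dosages)))
  if (!is.null(positions)) {
    stop_unless(length(positions) == ncol(dosages),
                "positions must match the number of markers")
    stop_unless(!is.unsorted(positions), "marker positions must be ordered")
  }
  structure(list(dosages = dosages,
                 positions = positions,
                 allele_freq = col_allele_freq(dosages),
                 animals = rownames(dosages),
                 markers = colnames(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("<genotype_matrix> %d animals x %d markers (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Write / read dosage genotypes as a tab-delimited matrix
#'
#' Header row of marker ids, first column of animal ids, dosages coded
#' 0/1/2 with `NA` for missing (PLINK `.raw`-style dosage convention).
#' Positions, when present, are stored in a sidecar `<file>.map` with
#' columns `marker` and `morgans`.
#'
#' @param geno a [genotype_matrix()].
#' @param file path of the tab-delimited file.
#' @return `write_genotypes()` returns `file` invisibly; `read_genotypes()`
#'   returns a [genotype_matrix()].
#' @export
write_genotypes <- function(geno, file) {
  df <- data.frame(animal = geno$animals, geno$dosages, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(geno$positions)) {
    utils::write.table(
      data.frame(marker = geno$markers, morgans = geno$positions),
      paste0(file, ".map"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  pos <- NULL
  mapfile <- paste0(file, ".map")
  if (file.exists(mapfile)) pos <- utils::read.delim(mapfile)$morgans
  genotype_matrix(m, positions = pos)
}

#' Write / read pedigree and phenotype tables as CSV
#'
#' Pedigree columns: `animal, sire, dam, family`; phenotype tables keep
#' whatever trait columns they carry plus `animal` and `cage`.
#'
#' @param x a data frame.
#' @param file CSV path.
#' @export
write_table_csv <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(file) utils::read.csv(file)
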
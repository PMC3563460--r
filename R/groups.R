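# Genetic-group definition by clustering on genomic distances, and tests
# for heterogeneity of predictive ability across groups.

#' Genomic relationship matrix (VanRaden type 1)
#'
#' `G = Z Z' / (2 sum p_i (1 - p_i))` with `Z = X - 2P` the
#' frequency-centred dosages.
#'
#' @param geno a [genotype_matrix()] or dosage matrix without missing values.
#' @return n x n matrix with animal ids as dimnames.
#' @export
g_matrix <- function(geno) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  stop_unless(!anyNA(X), "complete genotypes required")
  p <- col_allele_freq(X)
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  stop_unless(denom > 0, "all markers monomorphic")
  tcrossprod(Z) / denom
}

#' Genetic groups by Ward clustering of genomic distances
#'
#' Distances `d_ij^2 = G_ii + G_jj - 2 G_ij` are derived from the genomic
#' relationship matrix, clustered by Ward's hierarchical method; the
#' number of groups is chosen by maximising the Calinski-Harabasz
#' statistic over `k = 2..k_max` (computed in a classical
#' multidimensional-scaling embedding of the distances), and the Ward
#' labels are refined by k-means started from the Ward cluster centroids.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @param k_max largest number of groups considered, default 10.
#' @param embed_dim dimensions of the MDS embedding, default 10.
#' @return list with `labels` (named integer vector), `k`, `ch` (named
#'   vector of Calinski-Harabasz values), `ward_labels`, `embedding`.
#' @export
genetic_groups <- function(geno, k_max = 10, embed_dim = 10) {
  G <- g_matrix(geno)
  n <- nrow(G)
  stop_unless(n >= 2, "need at least two animals")
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d <- stats::as.dist(sqrt(pmax(d2, 0)))
  if (max(d) <= 1e-12) {
    warning("all animals genomically identical; single group")
    return(list(labels = stats::setNames(rep(1L, n), rownames(G)), k = 1L,
                ch = NULL, ward_labels = NULL, embedding = NULL))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  emb <- stats::cmdscale(d, k = min(embed_dim, n - 2))
  kk <- 2:min(k_max, n - 1)
  ch <- vapply(kk, function(k) {
    calinski_harabasz(emb, stats::cutree(hc, k))
  }, numeric(1))
  names(ch) <- kk
  k_best <- kk[which.max(ch)]
  ward <- stats::cutree(hc, k_best)
  centers <- apply(emb, 2, function(col) tapply(col, ward, mean))
  km <- stats::kmeans(emb, centers = matrix(centers, nrow = k_best))
  list(labels = stats::setNames(km$cluster, rownames(G)), k = k_best,
       ch = ch, ward_labels = stats::setNames(ward, rownames(G)),
       embedding = emb)
}

#' Calinski-Harabasz statistic of a clustering
#'
#' `(B / (k - 1)) / (W / (n - k))` with `B` and `W` the between- and
#' within-cluster sums of squared deviations in the given coordinates.
#'
#' @param coords numeric matrix (observations x dimensions).
#' @param labels cluster assignment.
#' @return the statistic (larger is better separated).
#' @export
calinski_harabasz <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    sub <- coords[labels == g, , drop = FALSE]
    ctr <- colMeans(sub)
    W <- W + sum(sweep(sub, 2, ctr)^2)
    B <- B + nrow(sub) * sum((ctr - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Tests for group differences in phenotypic variance and predictive ability
#'
#' Fligner-Killeen test of homogeneity of phenotypic variances across
#' groups, and, per replicate, a chi-square test of equality of the
#' within-group predictive abilities after Fisher's z transformation:
#' `X2 = sum (n_g - 3) (z_g - zbar_w)^2` with `z_g = atanh(r_g)`,
#' `zbar_w` the `(n_g - 3)`-weighted mean and `G - 1` degrees of freedom;
#' the resulting p-values are averaged across replicates.  Groups with
#' fewer than `min_n` validation animals are excluded (logged).
#'
#' @param group_stats data frame with columns `replicate`, `group`, `r`
#'   (within-group predictive ability), `n` (validation animals behind it).
#' @param phenotypes optional numeric vector for the variance test.
#' @param groups optional group labels aligned with `phenotypes`.
#' @param min_n smallest usable group size, default 4.
#' @return list with `fligner_p` (NA when no phenotypes given),
#'   `per_replicate` (data frame `replicate, statistic, df, p`),
#'   `mean_p`, `excluded` (data frame of dropped rows).
#' @export
group_tests <- function(group_stats, phenotypes = NULL, groups = NULL,
                        min_n = 4) {
  stop_unless(all(c("replicate", "group", "r", "n") %in% names(group_stats)),
              "group_stats needs replicate, group, r, n")
  fligner_p <- NA_real_
  if (!is.null(phenotypes)) {
    stop_unless(length(phenotypes) == length(groups),
                "phenotypes and groups must align")
    fligner_p <- stats::fligner.test(phenotypes, factor(groups))$p.value
  }
  usable <- group_stats$n >= min_n & is.finite(group_stats$r) &
    abs(group_stats$r) < 1
  excluded <- group_stats[!usable, , drop = FALSE]
  gs <- group_stats[usable, , drop = FALSE]
  per_rep <- do.call(rbind, lapply(split(gs, gs$replicate), function(sub) {
    if (nrow(sub) < 2)
      return(data.frame(replicate = sub$replicate[1], statistic = NA_real_,
                        df = NA_real_, p = NA_real_))
    z <- atanh(sub$r)
    w <- sub$n - 3
    zbar <- sum(w * z) / sum(w)
    stat <- sum(w * (z - zbar)^2)
    df <- nrow(sub) - 1
    data.frame(replicate = sub$replicate[1], statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  }))
  rownames(per_rep) <- NULL
  list(fligner_p = fligner_p, per_replicate = per_rep,
       mean_p = mean(per_rep$p, na.rm = TRUE), excluded = excluded)
}
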
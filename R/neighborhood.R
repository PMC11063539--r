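#' Spectral clustering of a similarity matrix
#'
#' Normalized-Laplacian spectral clustering treating the matrix as an
#' affinity: the top-`k` eigenvectors of `D^{-1/2} A D^{-1/2}` are
#' row-normalized and partitioned by seeded K-means.
#'
#' @param a A [similarity_matrix] (or symmetric nonnegative matrix).
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Integer seed making the K-means phase deterministic.
#' @return A [cluster_assignment].
#' @export
spectral_clusters <- function(a, k, seed = 0L) {
  vals <- sim_values(a)
  n <- nrow(vals)
  if (max(abs(vals - t(vals))) > 1e-8)
    stop("affinity matrix must be symmetric")
  if (min(vals) < -1e-12) stop("affinity matrix must be nonnegative")
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k >= n)
    stop("'k' must satisfy 2 <= k < n (n = ", n, ")")
  k <- as.integer(k)
  d <- rowSums(vals)
  d[d <= 0] <- 1e-300
  m <- vals / sqrt(d %o% d)
  ev <- eigen(m, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(u^2))
  nr[nr == 0] <- 1
  u <- u / nr
  km <- seeded_kmeans(u, k, seed)
  ids <- rownames(vals) %||% as.character(seq_len(n))
  cluster_assignment(km$cluster, sample_ids = ids, k = k)
}

#' Cluster geometry in the similarity-profile space
#'
#' Each patient is represented by its row of the current similarity matrix
#' (its similarity profile), so the geometry can be re-derived from the
#' updated per-omic matrices at every iteration. Computes per-cluster
#' centroids (member means), per-patient Euclidean distances to the own
#' cluster's centroid, and per-cluster mean centroid distances.
#'
#' @param a A [similarity_matrix] (or matrix) whose rows are patient
#'   coordinates.
#' @param ca A [cluster_assignment] for the same samples.
#' @return An object of class `cluster_geometry`: list with
#'   `representation` (n x n), `centroids` (k x n), `sizes` (k),
#'   `centroid_dists` (n), `mean_centroid_dist` (k). Singleton clusters get
#'   mean centroid distance 0.
#' @export
cluster_geometry <- function(a, ca) {
  vals <- sim_values(a)
  stopifnot(inherits(ca, "cluster_assignment"))
  if (nrow(vals) != length(ca$labels))
    stop("similarity matrix and cluster assignment sizes differ")
  if (!is.null(rownames(vals)) &&
      !identical(rownames(vals), ca$sample_ids))
    stop("sample ids of similarity matrix and assignment disagree")
  k <- ca$k
  lab <- ca$labels
  centroids <- matrix(0, k, ncol(vals))
  sizes <- tabulate(lab, k)
  for (c in seq_len(k)) {
    if (sizes[c] > 0)
      centroids[c, ] <- colMeans(vals[lab == c, , drop = FALSE])
  }
  dev <- vals - centroids[lab, , drop = FALSE]
  centroid_dists <- sqrt(rowSums(dev^2))
  mean_centroid_dist <- vapply(seq_len(k), function(c) {
    if (sizes[c] == 0) 0 else mean(centroid_dists[lab == c])
  }, numeric(1))
  structure(
    list(representation = vals, centroids = centroids, sizes = sizes,
         centroid_dists = centroid_dists,
         mean_centroid_dist = mean_centroid_dist, k = k),
    class = "cluster_geometry")
}

#' Inter-cluster separation measure
#'
#' Exponential separation between two clusters:
#' `D = exp(beta * ||v_i - v_j||^2 / (eta + 1))` with the normalizer
#' `eta = (mean_dist_i + mean_dist_j + ||v_i - v_j||) / 3`, where `v` are
#' cluster centroids and `mean_dist` the mean member-to-own-centroid
#' distances. `eta` scales the distance inside the exponential to reduce
#' scaling bias. `D >= 1` always, with `D = 1` for a cluster against
#' itself. A variant placing the normalizer outside the exponential
#' (`exp(beta * ||v_i - v_j||^2) / (eta + 1)`) is selectable.
#'
#' @param g A [cluster_geometry].
#' @param i,j Cluster indices (may be equal).
#' @param beta Positive separation gain; low values (0.1-1) are
#'   recommended; default 0.5.
#' @param eq3_parse `"normalized_exponent"` (default) or
#'   `"scaled_outside"`.
#' @return List with `d_value` and `eta`.
#' @export
inter_cluster_separation <- function(g, i, j, beta = 0.5,
                                     eq3_parse = c("normalized_exponent",
                                                   "scaled_outside")) {
  stopifnot(inherits(g, "cluster_geometry"))
  eq3_parse <- match.arg(eq3_parse)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar")
  cd <- sqrt(sum((g$centroids[i, ] - g$centroids[j, ])^2))
  eta <- (g$mean_centroid_dist[i] + g$mean_centroid_dist[j] + cd) / 3
  d_value <- if (eq3_parse == "normalized_exponent")
    exp(beta * cd^2 / (eta + 1))
  else
    exp(beta * cd^2) / (eta + 1)
  list(d_value = d_value, eta = eta)
}

#' Neighborhood profile similarity matrix
#'
#' Reweights a similarity matrix by cluster geometry so that pairs inside
#' tight, well-separated clusters are boosted relative to pairs split
#' across distant clusters:
#' `Abar[i, j] = 2 * A[i, j]^2 / (D(c_i, c_j) * (mu + md_i + md_j))`
#' where `D` is the inter-cluster separation of the two patients' clusters
#' and `md` their clusters' mean member-to-centroid distances. The positive
#' `mu` guards the denominator when all members coincide with their
#' centroids. With `mu = 1` the denominator is at least 1, so
#' `Abar <= 2 * A^2 <= 2`. An additive denominator variant
#' (`D + mu + md_i + md_j`) is selectable.
#'
#' @param a A [similarity_matrix] (current per-omic similarities).
#' @param g The [cluster_geometry] derived from `a`.
#' @param ca The [cluster_assignment] the geometry was built from.
#' @param beta Positive inter-cluster separation gain (default 0.5).
#' @param mu Positive singularity guard (default 1).
#' @param eq2_parse `"multiplicative"` (default) or `"additive"`
#'   denominator grouping.
#' @param eq3_parse Passed to [inter_cluster_separation()].
#' @return A [similarity_matrix] with `role = "neighborhood"`.
#' @export
neighborhood_matrix <- function(a, g, ca, beta = 0.5, mu = 1,
                                eq2_parse = c("multiplicative", "additive"),
                                eq3_parse = c("normalized_exponent",
                                              "scaled_outside")) {
  eq2_parse <- match.arg(eq2_parse)
  eq3_parse <- match.arg(eq3_parse)
  vals <- sim_values(a)
  stopifnot(inherits(g, "cluster_geometry"),
            inherits(ca, "cluster_assignment"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("'mu' must be positive: it guards against a vanishing denominator")
  k <- g$k
  lab <- ca$labels
  dmat <- matrix(1, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    dmat[i, j] <- inter_cluster_separation(g, i, j, beta = beta,
                                           eq3_parse = eq3_parse)$d_value
  md_sum <- outer(g$mean_centroid_dist[lab], g$mean_centroid_dist[lab], "+")
  dpair <- matrix(dmat[lab, lab], nrow = length(lab))
  denom <- if (eq2_parse == "multiplicative") dpair * (mu + md_sum)
           else dpair + mu + md_sum
  abar <- 2 * vals^2 / denom
  abar <- (abar + t(abar)) / 2
  dimnames(abar) <- dimnames(vals)
  similarity_matrix(abar, role = "neighborhood",
                    omic_name = if (inherits(a, "similarity_matrix"))
                      a$omic_name else "omic")
}
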
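#' Fusion configuration
#'
#' Bundles and validates all tunable parameters of the iterative
#' cluster-fusion pipeline.
#'
#' @param k Number of clusters (>= 2); used both for the per-iteration
#'   spectral clustering and the final K-means.
#' @param alpha Positive kernel bandwidth for [pairwise_similarity()]
#'   (default 1.5), shared across omics.
#' @param beta Positive inter-cluster separation gain (default 0.5;
#'   recommended range 0.1-1).
#' @param mu Positive singularity guard in the neighborhood denominator
#'   (default 1).
#' @param iterations Number of message-passing iterations (default 7, where
#'   clusters are typically well consolidated on separable data).
#' @param seed Integer master seed; all stochastic stages derive
#'   deterministic sub-seeds from it.
#' @param rescale_each_iteration Divide each updated matrix by its maximum
#'   entry after every fusion step (default `TRUE`), keeping entries in
#'   \[0, 1\].
#' @param operator Message-operator form used in [fusion_step()]:
#'   `"self_weighted"` (default; rows of the neighborhood matrix are
#'   normalized to sum one and blended with the identity) or `"raw"` (the
#'   neighborhood matrix is used unnormalized).
#' @param smoothing_weight Weight in (0, 1) of the normalized neighborhood
#'   component of the self-weighted operator (default 0.2).
#' @param eq2_parse,eq3_parse Parse variants, see [neighborhood_matrix()]
#'   and [inter_cluster_separation()].
#' @param phase2_clusterer `"spectral"` (default) or `"kmeans"`
#'   (K-means on the rows of the similarity matrix) for the per-iteration
#'   clustering.
#' @param combine `"sum"` (default) or `"average"` over the other omics in
#'   the fusion update.
#' @param squared Kernel exponent variant, see [pairwise_similarity()].
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(k, alpha = 1.5, beta = 0.5, mu = 1,
                          iterations = 7L, seed = 0L,
                          rescale_each_iteration = TRUE,
                          operator = c("self_weighted", "raw"),
                          smoothing_weight = 0.2,
                          eq2_parse = c("multiplicative", "additive"),
                          eq3_parse = c("normalized_exponent",
                                        "scaled_outside"),
                          phase2_clusterer = c("spectral", "kmeans"),
                          combine = c("sum", "average"),
                          squared = TRUE) {
  if (missing(k)) stop("'k' (number of clusters) is required")
  if (!is.numeric(k) || length(k) != 1L || k < 2L)
    stop("'k' must be an integer >= 2")
  for (nm in c("alpha", "beta", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("'", nm, "' must be a positive scalar")
  }
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1L)
    stop("'iterations' must be an integer >= 1")
  if (!is.numeric(smoothing_weight) || smoothing_weight <= 0 ||
      smoothing_weight >= 1)
    stop("'smoothing_weight' must be in (0, 1)")
  structure(
    list(k = as.integer(k), alpha = alpha, beta = beta, mu = mu,
         iterations = as.integer(iterations), seed = as.integer(seed),
         rescale_each_iteration = isTRUE(rescale_each_iteration),
         operator = match.arg(operator),
         smoothing_weight = smoothing_weight,
         eq2_parse = match.arg(eq2_parse),
         eq3_parse = match.arg(eq3_parse),
         phase2_clusterer = match.arg(phase2_clusterer),
         combine = match.arg(combine),
         squared = isTRUE(squared)),
    class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf(paste0("<fusion_config> k=%d alpha=%g beta=%g mu=%g ",
                     "iterations=%d seed=%d operator=%s\n"),
              x$k, x$alpha, x$beta, x$mu, x$iterations, x$seed, x$operator))
  invisible(x)
}

# build the per-omic message operator from a neighborhood matrix
message_operator <- function(abar, operator, smoothing_weight) {
  m <- sim_values(abar)
  if (operator == "raw") return(m)
  rs <- rowSums(m)
  rs[rs <= 0] <- 1
  r <- m / rs
  (1 - smoothing_weight) * diag(nrow(m)) + smoothing_weight * r
}

#' One cross-omic fusion step
#'
#' Updates every omic's similarity matrix by passing messages through its
#' own neighborhood operator: for each omic `o`,
#' `A_new^o = sum over o' != o of S^o %*% A^{o'} %*% t(S^o)` where `S^o` is
#' the message operator derived from the omic's neighborhood matrix. With
#' the default `"self_weighted"` operator, `S` blends the identity with the
#' row-normalized neighborhood matrix, so the update diffuses each other
#' omic's similarities over the omic's own neighborhoods while retaining
#' each patient's own profile; with `operator = "raw"` the neighborhood
#' matrix itself is the operator and the update is the plain triple-product
#' sum. The result is symmetrized as `(M + t(M)) / 2` to absorb
#' floating-point drift and optionally divided by its maximum entry.
#'
#' @param a_list List (>= 2) of current per-omic [similarity_matrix]
#'   objects (or matrices), aligned by omic with `abar_list`.
#' @param abar_list List of the omics' neighborhood matrices.
#' @param operator,smoothing_weight,combine,rescale See [fusion_config()];
#'   `rescale` maps to `rescale_each_iteration`.
#' @return List of updated [similarity_matrix] objects
#'   (`role = "fused"`).
#' @export
fusion_step <- function(a_list, abar_list,
                        operator = c("self_weighted", "raw"),
                        smoothing_weight = 0.2,
                        combine = c("sum", "average"), rescale = TRUE) {
  operator <- match.arg(operator)
  combine <- match.arg(combine)
  n_omics <- length(a_list)
  if (n_omics < 2L)
    stop("message passing needs at least two omic layers")
  if (length(abar_list) != n_omics)
    stop("'a_list' and 'abar_list' must be aligned by omic")
  avals <- lapply(a_list, sim_values)
  dims <- vapply(avals, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("all similarity matrices must have identical size")
  out <- vector("list", n_omics)
  for (o in seq_len(n_omics)) {
    s <- message_operator(abar_list[[o]], operator, smoothing_weight)
    if (nrow(s) != dims[1L]) stop("neighborhood matrix size mismatch")
    m <- matrix(0, dims[1L], dims[1L])
    for (o2 in seq_len(n_omics)) {
      if (o2 == o) next
      m <- m + s %*% avals[[o2]] %*% t(s)
    }
    if (combine == "average") m <- m / (n_omics - 1L)
    m <- (m + t(m)) / 2
    if (rescale) {
      mx <- max(m)
      if (mx > 0) m <- m / mx
    }
    dimnames(m) <- dimnames(avals[[o]])
    omic <- if (inherits(a_list[[o]], "similarity_matrix"))
      a_list[[o]]$omic_name else paste0("omic", o)
    out[[o]] <- similarity_matrix(m, role = "fused", omic_name = omic)
  }
  out
}

#' Integrate per-omic similarity matrices
#'
#' Elementwise mean of the (final) per-omic similarity matrices, producing
#' the single integrated patient-patient matrix that represents all omic
#' profiles. Works for any number (>= 2) of omics.
#'
#' @param a_list List of aligned [similarity_matrix] objects or matrices.
#' @return A [similarity_matrix] with `role = "integrated"`.
#' @export
integrate_similarity <- function(a_list) {
  if (length(a_list) < 2L) stop("need at least two matrices to integrate")
  avals <- lapply(a_list, sim_values)
  dims <- vapply(avals, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("matrix size mismatch")
  m <- Reduce(`+`, avals) / length(avals)
  m <- (m + t(m)) / 2
  if (is.null(dimnames(m))) dimnames(m) <- dimnames(avals[[1L]])
  similarity_matrix(m, role = "integrated", omic_name = "integrated")
}

#' Final K-means subtype assignment
#'
#' K-means on the rows of the integrated similarity matrix (each patient
#' represented by its integrated similarity profile), with multiple
#' restarts and a fixed seed.
#'
#' @param integrated A [similarity_matrix] (typically
#'   `role = "integrated"`).
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Integer seed.
#' @param nstart Number of random restarts (default 20).
#' @return A [cluster_assignment].
#' @export
final_kmeans <- function(integrated, k, seed = 0L, nstart = 20L) {
  vals <- sim_values(integrated)
  n <- nrow(vals)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k >= n)
    stop("'k' must satisfy 2 <= k < n (n = ", n, ")")
  km <- seeded_kmeans(vals, as.integer(k), seed, nstart = nstart)
  ids <- rownames(vals) %||% as.character(seq_len(n))
  cluster_assignment(km$cluster, sample_ids = ids, k = as.integer(k))
}

#' Run the full iterative cluster-fusion pipeline
#'
#' Phase 1 builds one Gaussian-kernel similarity matrix per omic. Then, for
#' each of `config$iterations` iterations, Phase 2 clusters every omic's
#' current matrix (spectral clustering at `k`), derives its cluster
#' geometry and neighborhood matrix, and Phase 3 updates each omic's matrix
#' by cross-omic message passing ([fusion_step()]). Finally the per-omic
#' matrices are averaged ([integrate_similarity()]) and the integrated
#' matrix is clustered with K-means ([final_kmeans()]). The silhouette of a
#' `k`-clustering of the integrated matrix is recorded after every
#' iteration, supporting convergence monitoring: on separable data the
#' trace increases as the clusters consolidate.
#'
#' @param layers List (>= 2) of preprocessed, sample-aligned
#'   [omics_matrix] objects (no missing values, identical sample order).
#' @param config A [fusion_config].
#' @return An object of class `fusion_result`: list with `integrated`
#'   ([similarity_matrix]), `assignment` ([cluster_assignment]),
#'   `per_iteration_silhouette` (numeric, one value per iteration),
#'   `final_per_omic` (list of per-omic fused matrices) and `config`.
#' @examples
#' spec <- simulation_spec(n_per_cluster = c(15, 15, 15), seed = 1)
#' sim <- generate_multiomic(spec)
#' res <- run_icluf(sim$layers, fusion_config(k = 3, seed = 1))
#' adjusted_rand_index(res$assignment, sim$truth)
#' @export
run_icluf <- function(layers, config) {
  stopifnot(inherits(config, "fusion_config"))
  if (!is.list(layers) || length(layers) < 2L)
    stop("need at least two omic layers")
  lapply(layers, function(l) stopifnot(inherits(l, "omics_matrix")))
  ids <- layers[[1L]]$sample_ids
  for (l in layers[-1L])
    if (!identical(l$sample_ids, ids))
      stop("layers are not sample-aligned; run align_cohort() first")
  n <- length(ids)
  if (config$k >= n) stop("'k' must be smaller than the number of samples")

  a_list <- lapply(layers, pairwise_similarity, alpha = config$alpha,
                   squared = config$squared)
  sil_trace <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    abar_list <- vector("list", length(a_list))
    for (o in seq_along(a_list)) {
      ca_o <- if (config$phase2_clusterer == "spectral")
        spectral_clusters(a_list[[o]], config$k,
                          seed = sub_seed(config$seed, it, o))
      else
        final_kmeans(a_list[[o]], config$k,
                     seed = sub_seed(config$seed, it, o))
      g_o <- cluster_geometry(a_list[[o]], ca_o)
      abar_list[[o]] <- neighborhood_matrix(
        a_list[[o]], g_o, ca_o, beta = config$beta, mu = config$mu,
        eq2_parse = config$eq2_parse, eq3_parse = config$eq3_parse)
    }
    a_list <- fusion_step(a_list, abar_list, operator = config$operator,
                          smoothing_weight = config$smoothing_weight,
                          combine = config$combine,
                          rescale = config$rescale_each_iteration)
    for (m in a_list)
      if (any(!is.finite(m$values)))
        stop("non-finite similarity values at iteration ", it)
    a_int <- integrate_similarity(a_list)
    ca_it <- final_kmeans(a_int, config$k, seed = config$seed)
    sil_trace[it] <- silhouette_score(a_int, ca_it)
  }
  integrated <- integrate_similarity(a_list)
  assignment <- final_kmeans(integrated, config$k, seed = config$seed)
  structure(
    list(integrated = integrated, assignment = assignment,
         per_iteration_silhouette = sil_trace, final_per_omic = a_list,
         config = config),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d samples, k = %d, %d iterations\n",
              length(x$assignment$labels), x$config$k, x$config$iterations))
  cat("cluster sizes:",
      paste(tabulate(x$assignment$labels, x$config$k), collapse = ", "), "\n")
  cat("silhouette trace:",
      paste(sprintf("%.3f", x$per_iteration_silhouette), collapse = " "),
      "\n")
  invisible(x)
}
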
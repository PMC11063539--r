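# pair-counting contingency between two label vectors
pair_counts <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  list(tab = tab, n = n,
       sum_ij = sum(choose(tab, 2)),
       sum_a = sum(choose(rowSums(tab), 2)),
       sum_b = sum(choose(colSums(tab), 2)),
       total = choose(n, 2))
}

check_same_samples <- function(a, b) {
  la <- label_values(a)
  lb <- label_values(b)
  if (length(la) != length(lb))
    stop("the two partitions cover different numbers of samples")
  if (inherits(a, "cluster_assignment") && inherits(b, "cluster_assignment") &&
      !identical(a$sample_ids, b$sample_ids))
    stop("the two partitions cover different samples (or different order)")
  list(a = la, b = lb)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same samples: 1 for identical partitions, about 0 for independent ones.
#' Symmetric in its arguments and invariant to label permutation.
#'
#' @param a,b [cluster_assignment] objects (or plain label vectors) over
#'   the same samples in the same order.
#' @return Numeric scalar, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  l <- check_same_samples(a, b)
  pc <- pair_counts(l$a, l$b)
  expected <- pc$sum_a * pc$sum_b / pc$total
  denom <- (pc$sum_a + pc$sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in pairs
  (pc$sum_ij - expected) / denom
}

#' Fowlkes-Mallows score
#'
#' Geometric mean of pairwise precision and recall between two partitions:
#' `TP / sqrt(P_a * P_b)` where `TP` counts sample pairs co-clustered in
#' both partitions and `P_a`, `P_b` the pairs co-clustered in each. Ranges
#' in \[0, 1\]; 1 for identical partitions.
#'
#' @inheritParams adjusted_rand_index
#' @return Numeric scalar in \[0, 1\].
#' @export
fowlkes_mallows <- function(a, b) {
  l <- check_same_samples(a, b)
  pc <- pair_counts(l$a, l$b)
  if (pc$sum_a == 0 || pc$sum_b == 0) return(0)
  pc$sum_ij / sqrt(pc$sum_a * pc$sum_b)
}

#' Mean silhouette score of a clustering
#'
#' Per-sample silhouette `(b - a) / max(a, b)` with `a` the mean distance
#' to the own cluster's other members and `b` the smallest mean distance to
#' another cluster, averaged over samples. Distances are Euclidean between
#' rows of the supplied matrix (consistent with the representation used by
#' [final_kmeans()]); a `(1 - similarity)` dissimilarity variant is
#' available. Samples in singleton clusters score 0.
#'
#' @param integrated A [similarity_matrix] (or matrix) whose rows represent
#'   the samples.
#' @param ca A [cluster_assignment] with `k >= 2` nonempty clusters.
#' @param distance `"euclidean"` (default) on matrix rows, or
#'   `"one_minus_similarity"` to use `1 - values` directly as
#'   dissimilarities.
#' @return Numeric scalar in \[-1, 1\].
#' @export
silhouette_score <- function(integrated, ca,
                             distance = c("euclidean",
                                          "one_minus_similarity")) {
  distance <- match.arg(distance)
  vals <- sim_values(integrated)
  lab <- label_values(ca)
  if (length(lab) != nrow(vals))
    stop("assignment and matrix cover different numbers of samples")
  k <- max(lab)
  if (length(unique(lab)) < 2L)
    stop("silhouette undefined for a single cluster")
  d <- if (distance == "euclidean") as.matrix(stats::dist(vals))
       else 1 - vals
  n <- nrow(d)
  sizes <- tabulate(lab, k)
  # mean distance from each sample to every cluster, column per cluster
  cluster_means <- vapply(seq_len(k), function(c) {
    if (sizes[c] == 0) return(rep(Inf, n))
    rowSums(d[, lab == c, drop = FALSE]) / sizes[c]
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a_i <- cluster_means[i, ci] * sizes[ci] / (sizes[ci] - 1L)
    b_i <- min(cluster_means[i, -ci])
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Multi-group log-rank test
#'
#' K-sample log-rank (score) test for survival differences between
#' clusters: at every distinct event time the observed events per group are
#' compared with their expectation under the pooled risk set, tied events
#' handled with the standard hypergeometric variance. The statistic is
#' chi-squared with `K - 1` degrees of freedom under the null of equal
#' survival curves.
#'
#' @param surv A [survival_table].
#' @param ca A [cluster_assignment] (or group label vector) for the same
#'   samples; when both carry sample ids the survival rows are matched by
#'   id.
#' @return List with `stat`, `df`, `p`, and the per-group
#'   observed/expected event counts (`observed`, `expected`).
#' @export
logrank_test <- function(surv, ca) {
  stopifnot(inherits(surv, "survival_table"))
  lab <- label_values(ca)
  if (inherits(ca, "cluster_assignment")) {
    rows <- match(ca$sample_ids, surv$sample_id)
    if (anyNA(rows))
      stop("samples missing from the survival table: ",
           paste(utils::head(ca$sample_ids[is.na(rows)], 5), collapse = ", "))
    surv <- surv[rows, ]
  } else if (length(lab) != nrow(surv)) {
    stop("group labels and survival table cover different numbers of samples")
  }
  groups <- sort(unique(lab))
  ng <- length(groups)
  if (ng < 2L) stop("need at least two nonempty groups")
  if (sum(surv$event) == 0L)
    stop("no events observed; log-rank test undefined")
  gidx <- match(lab, groups)
  time <- surv$time
  event <- surv$event
  tt <- sort(unique(time[event == 1]))
  obs <- exp_ <- numeric(ng)
  v <- matrix(0, ng, ng)
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    if (n_t < 1L) next
    n_tg <- tabulate(gidx[at_risk], ng)
    here <- at_risk & time == t & event == 1
    d_t <- sum(here)
    d_tg <- tabulate(gidx[here], ng)
    obs <- obs + d_tg
    exp_ <- exp_ + d_t * n_tg / n_t
    if (n_t > 1L) {
      frac <- n_tg / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) * (diag(frac) - frac %o% frac)
      v <- v + vt
    }
  }
  z <- (obs - exp_)[-ng]
  vsub <- v[-ng, -ng, drop = FALSE]
  # pseudo-inverse guards against a numerically singular variance matrix
  sv <- svd(vsub)
  pos <- sv$d > max(sv$d) * 1e-12
  vinv <- if (any(pos))
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  else matrix(0, ng - 1L, ng - 1L)
  stat <- drop(t(z) %*% vinv %*% z)
  df <- ng - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = stats::setNames(obs, groups),
       expected = stats::setNames(exp_, groups))
}

#' Kaplan-Meier curves per cluster
#'
#' Product-limit survival estimate for every cluster, returned as a tidy
#' step-function table suitable for any plotting tool.
#'
#' @inheritParams logrank_test
#' @return data.frame with columns `group`, `time`, `n_at_risk`,
#'   `n_events`, `survival`; survival is non-increasing from 1 within each
#'   group.
#' @export
km_curves <- function(surv, ca) {
  stopifnot(inherits(surv, "survival_table"))
  lab <- label_values(ca)
  if (inherits(ca, "cluster_assignment")) {
    rows <- match(ca$sample_ids, surv$sample_id)
    if (anyNA(rows)) stop("samples missing from the survival table")
    surv <- surv[rows, ]
  }
  grp <- factor(lab)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  if (is.null(fit$strata)) {
    strata_id <- rep(levels(grp)[1L], length(fit$time))
  } else {
    strata_id <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata_id, time = fit$time, n_at_risk = fit$n.risk,
             n_events = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Survival comparisons over all cluster subsets
#'
#' For every combination of `size` clusters (for each requested size),
#' restricts the cohort to the samples in those clusters and runs the
#' multi-group log-rank test, mirroring pairwise and higher-order subtype
#' survival comparisons. With `k = 5` clusters, subset sizes 2, 3 and 4
#' yield 10, 10 and 5 tests.
#'
#' @inheritParams logrank_test
#' @param subset_sizes Integer vector of subset sizes, each `< k`.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (default `FALSE`; raw p-values are always reported).
#' @return data.frame with columns `subset_size`, `clusters` (e.g.
#'   `"1+3"`), `stat`, `df`, `p` (and `p_bh` if `adjust`).
#' @export
cluster_subset_survival <- function(surv, ca, subset_sizes, adjust = FALSE) {
  stopifnot(inherits(surv, "survival_table"),
            inherits(ca, "cluster_assignment"))
  k <- ca$k
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes >= k) || any(subset_sizes < 2L))
    stop("subset sizes must lie in 2..(k-1) (k = ", k, ")")
  res <- list()
  for (size in subset_sizes) {
    combs <- utils::combn(seq_len(k), size)
    for (ci in seq_len(ncol(combs))) {
      members <- ca$labels %in% combs[, ci]
      sub_ca <- cluster_assignment(
        match(ca$labels[members], combs[, ci]),
        sample_ids = ca$sample_ids[members], k = size)
      lr <- tryCatch(logrank_test(surv, sub_ca),
                     error = function(e) list(stat = NA_real_,
                                              df = size - 1L, p = NA_real_))
      res[[length(res) + 1L]] <- data.frame(
        subset_size = size,
        clusters = paste(combs[, ci], collapse = "+"),
        stat = lr$stat, df = lr$df, p = lr$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Evaluation report for a clustering
#'
#' Bundles the cluster-quality metrics for one predicted partition:
#' silhouette on the integrated matrix, agreement with a reference
#' partition (ARI, Fowlkes-Mallows) when available, and the multi-group
#' log-rank test when survival data are available.
#'
#' @param ca Predicted [cluster_assignment].
#' @param integrated Optional [similarity_matrix] for the silhouette.
#' @param reference Optional reference [cluster_assignment] (e.g. known
#'   subtypes or planted labels).
#' @param surv Optional [survival_table].
#' @return Named list with whichever of `silhouette`, `ari`, `fm`,
#'   `logrank_stat`, `logrank_df`, `logrank_p` could be computed.
#' @export
evaluation_report <- function(ca, integrated = NULL, reference = NULL,
                              surv = NULL) {
  stopifnot(inherits(ca, "cluster_assignment"))
  out <- list()
  if (!is.null(integrated))
    out$silhouette <- silhouette_score(integrated, ca)
  if (!is.null(reference)) {
    out$ari <- adjusted_rand_index(ca, reference)
    out$fm <- fowlkes_mallows(ca, reference)
  }
  if (!is.null(surv)) {
    lr <- logrank_test(surv, ca)
    out$logrank_stat <- lr$stat
    out$logrank_df <- lr$df
    out$logrank_p <- lr$p
  }
  out
}
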
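#' Random-forest Gini importance of an omic's features
#'
#' Trains a seeded random-forest classifier predicting the cluster labels
#' from the omic's feature matrix and returns each feature's mean decrease
#' in Gini impurity, normalized to sum to one within the forest.
#'
#' @param m An [omics_matrix] (no missing values).
#' @param labels A [cluster_assignment] (or label vector) with at least two
#'   classes, e.g. the subtypes predicted by [run_icluf()].
#' @param seed Integer seed.
#' @param n_trees Number of trees (default 500). Features per split follow
#'   the classification default (square root of the feature count).
#' @return Named numeric vector of normalized Gini importances (one per
#'   feature, nonnegative, summing to 1).
#' @export
gini_importance <- function(m, labels, seed = 0L, n_trees = 500L) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$values)) stop("omic contains missing values")
  lab <- label_values(labels)
  if (inherits(labels, "cluster_assignment") &&
      !identical(labels$sample_ids, m$sample_ids))
    stop("label sample ids do not match the omic matrix")
  if (length(lab) != nrow(m$values))
    stop("labels and matrix cover different numbers of samples")
  if (length(unique(lab)) < 2L)
    stop("need at least two classes to train the forest")
  rf <- withr::with_seed(as.integer(seed), {
    randomForest::randomForest(x = m$values, y = factor(lab),
                               ntree = as.integer(n_trees))
  })
  gi <- randomForest::importance(rf, type = 2)[, 1L]
  total <- sum(gi)
  if (total <= 0) return(stats::setNames(rep(0, length(gi)), names(gi)))
  gi / total
}

#' Per-omic contribution to the predicted subtypes
#'
#' Aggregates per-feature Gini importances into one contribution score per
#' omic: within each omic the features are sorted by importance and the top
#' fraction (default 25%, ceiling so small omics keep at least one feature)
#' is summed; the per-omic sums are then min-max normalized across omics so
#' the least informative omic maps to 0 and the most informative to 1.
#'
#' @param reports Named list (>= 2 omics) mapping omic name to the feature
#'   importance vector returned by [gini_importance()].
#' @param top_fraction Fraction of top features summed per omic
#'   (default 0.25).
#' @return An object of class `importance_report`: list with `per_feature`
#'   (the input), `per_omic_raw` (top-fraction sums), `per_omic_normalized`
#'   (min-max normalized across omics), `n_top` (features kept per omic)
#'   and `top_fraction`.
#' @export
omic_contribution <- function(reports, top_fraction = 0.25) {
  if (!is.list(reports) || length(reports) < 2L)
    stop("min-max normalization needs at least two omics")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("'reports' must be a named list (one entry per omic)")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]")
  raw <- vapply(reports, function(gi) {
    n_top <- ceiling(top_fraction * length(gi))
    sum(sort(gi, decreasing = TRUE)[seq_len(n_top)])
  }, numeric(1))
  n_top <- vapply(reports, function(gi)
    as.integer(ceiling(top_fraction * length(gi))), integer(1))
  rng <- range(raw)
  normalized <- if (diff(rng) == 0) {
    warning("all omics have identical raw contributions; ",
            "min-max normalization degenerate")
    stats::setNames(rep(0.5, length(raw)), names(raw))
  } else {
    (raw - rng[1L]) / diff(rng)
  }
  structure(
    list(per_feature = reports, per_omic_raw = raw,
         per_omic_normalized = normalized, n_top = n_top,
         top_fraction = top_fraction),
    class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> per-omic contributions (min-max normalized):\n")
  for (nm in names(x$per_omic_normalized))
    cat(sprintf("  %-14s raw %.4f  normalized %.3f  (top %d features)\n",
                nm, x$per_omic_raw[[nm]], x$per_omic_normalized[[nm]],
                x$n_top[[nm]]))
  invisible(x)
}
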
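#' Write / read cluster labels CSV
#'
#' Two-column CSV (`sample_id`, `cluster`) used by the command-line
#' interface and the reproducibility manifest.
#'
#' @param ca A [cluster_assignment].
#' @param path Output file path.
#' @return `path` invisibly (write) or a [cluster_assignment] (read).
#' @export
write_cluster_labels <- function(ca, path) {
  stopifnot(inherits(ca, "cluster_assignment"))
  utils::write.csv(data.frame(sample_id = ca$sample_ids,
                              cluster = ca$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cluster_labels
#' @export
read_cluster_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cluster") %in% colnames(df)))
    stop("labels file must have columns sample_id, cluster")
  cluster_assignment(df$cluster, sample_ids = df$sample_id)
}

#' Run the full pipeline from files and write all outputs
#'
#' End-to-end driver: reads the omic matrices (and optional survival table
#' and reference labels), aligns the cohort, filters features by
#' missingness, runs [run_icluf()], and writes cluster labels, the
#' integrated matrix, the per-iteration silhouette trace, an evaluation
#' report (when survival and/or reference labels are available), a
#' preprocessing report and a YAML run manifest from which the run can be
#' reproduced bit-identically.
#'
#' @param omic_paths Named character vector (>= 2) mapping omic name to the
#'   matrix file path.
#' @param k Number of clusters.
#' @param out_dir Output directory (created if absent).
#' @param survival_path Optional survival table path.
#' @param truth_path Optional reference labels path (CSV with `sample_id`,
#'   `cluster`).
#' @param orientation Matrix orientation, see [read_omics_matrix()].
#' @param max_bad_fraction Missingness/zero filter threshold (default
#'   0.20).
#' @param impute Imputation rule after filtering, see
#'   [filter_features_by_missingness()].
#' @param ... Further arguments passed to [fusion_config()] (`alpha`,
#'   `beta`, `mu`, `iterations`, `seed`, variant switches).
#' @return A [run_icluf()] result, invisibly; side effect: files under
#'   `out_dir` (`labels.csv`, `integrated_matrix.csv`, `silhouette.json`,
#'   `preprocess_report.json`, `evaluation.json` when applicable,
#'   `manifest.yaml`).
#' @export
icluf_run <- function(omic_paths, k, out_dir, survival_path = NULL,
                      truth_path = NULL,
                      orientation = "samples_in_rows",
                      max_bad_fraction = 0.20, impute = "mean", ...) {
  if (length(omic_paths) < 2L || is.null(names(omic_paths)))
    stop("'omic_paths' must be a named vector of at least two files")
  config <- fusion_config(k = k, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layers <- mapply(function(path, nm)
    read_omics_matrix(path, orientation = orientation, omic_name = nm),
    omic_paths, names(omic_paths), SIMPLIFY = FALSE)
  surv <- if (!is.null(survival_path)) read_survival_table(survival_path)
  aligned <- align_cohort(layers, surv)
  filtered <- lapply(aligned$layers, filter_features_by_missingness,
                     max_bad_fraction = max_bad_fraction, impute = impute)
  pre_report <- list(
    samples_analyzed = length(filtered[[1L]]$sample_ids),
    samples_dropped = as.list(aligned$n_dropped),
    features_dropped = stats::setNames(
      lapply(filtered, function(f) attr(f, "n_dropped")),
      vapply(filtered, function(f) f$omic_name, character(1))))
  jsonlite::write_json(pre_report,
                       file.path(out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  result <- run_icluf(filtered, config)
  write_cluster_labels(result$assignment, file.path(out_dir, "labels.csv"))
  write_similarity_matrix(result$integrated,
                          file.path(out_dir, "integrated_matrix.csv"))
  jsonlite::write_json(
    list(per_iteration_silhouette = result$per_iteration_silhouette),
    file.path(out_dir, "silhouette.json"), auto_unbox = TRUE, digits = NA)

  reference <- if (!is.null(truth_path)) {
    truth <- read_cluster_labels(truth_path)
    rows <- match(result$assignment$sample_ids, truth$sample_ids)
    if (anyNA(rows)) stop("reference labels missing some analyzed samples")
    cluster_assignment(truth$labels[rows],
                       sample_ids = result$assignment$sample_ids,
                       k = truth$k)
  }
  if (!is.null(aligned$survival) || !is.null(reference)) {
    report <- evaluation_report(result$assignment,
                                integrated = result$integrated,
                                reference = reference,
                                surv = aligned$survival)
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "iCluF",
    version = as.character(utils::packageVersion("iCluF")),
    inputs = list(
      omics = as.list(stats::setNames(normalizePath(omic_paths),
                                      names(omic_paths))),
      survival = if (!is.null(survival_path)) normalizePath(survival_path),
      truth = if (!is.null(truth_path)) normalizePath(truth_path),
      orientation = orientation,
      max_bad_fraction = max_bad_fraction,
      impute = impute),
    config = unclass(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(result)
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.yaml` written by [icluf_run()] and repeats the run
#' with identical inputs and configuration; with the same seed all numeric
#' outputs are reproduced bit-identically.
#'
#' @param manifest_path Path to a manifest YAML file.
#' @param out_dir Output directory for the repeated run.
#' @return See [icluf_run()].
#' @export
icluf_run_from_manifest <- function(manifest_path, out_dir) {
  mf <- yaml::read_yaml(manifest_path)
  cfg <- mf$config
  icluf_run(
    omic_paths = unlist(mf$inputs$omics), k = cfg$k, out_dir = out_dir,
    survival_path = mf$inputs$survival, truth_path = mf$inputs$truth,
    orientation = mf$inputs$orientation,
    max_bad_fraction = mf$inputs$max_bad_fraction,
    impute = mf$inputs$impute,
    alpha = cfg$alpha, beta = cfg$beta, mu = cfg$mu,
    iterations = cfg$iterations, seed = cfg$seed,
    rescale_each_iteration = cfg$rescale_each_iteration,
    operator = cfg$operator, smoothing_weight = cfg$smoothing_weight,
    eq2_parse = cfg$eq2_parse, eq3_parse = cfg$eq3_parse,
    phase2_clusterer = cfg$phase2_clusterer, combine = cfg$combine,
    squared = cfg$squared)
}
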
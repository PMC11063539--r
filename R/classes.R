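#' Construct an omics matrix
#'
#' Container for a single omic layer: a numeric samples-by-features matrix
#' with unique sample and feature identifiers and an omic label. Missing
#' measurements are represented as `NA`.
#'
#' @param values Numeric matrix, rows = samples, columns = features. Must
#'   carry row names (sample ids) and column names (feature ids).
#' @param omic_name Label for the layer, e.g. `"mRNA"`, `"miRNA"`,
#'   `"methylation"`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `omic_name`, `sample_ids`, `feature_ids`.
#' @examples
#' x <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
#' om <- omics_matrix(x, "mRNA")
#' @export
omics_matrix <- function(values, omic_name) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty omics matrix (", omic_name, ")")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample ids as row names and feature ids as column names")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicated sample id(s) in omic '", omic_name, "': ",
         paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop("duplicated feature id(s) in omic '", omic_name, "': ",
         paste(dup_f, collapse = ", "))
  structure(
    list(values = values, omic_name = as.character(omic_name),
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s'> %d samples x %d features", x$omic_name,
              nrow(x$values), ncol(x$values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf(" (%d missing entries)", n_na))
  cat("\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Construct a patient-patient similarity matrix
#'
#' Square symmetric nonnegative matrix of pairwise patient similarities,
#' tagged by its role in the pipeline: `"original"` (kernel similarities,
#' unit diagonal, entries in \[0, 1\]), `"neighborhood"` (cluster-geometry
#' reweighted), `"fused"` (after cross-omic message passing) or
#' `"integrated"` (average across omics).
#'
#' @param values Square numeric matrix with identical row and column names
#'   (sample ids).
#' @param role One of `"original"`, `"neighborhood"`, `"fused"`,
#'   `"integrated"`.
#' @param omic_name Label of the omic the matrix derives from, or
#'   `"integrated"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values,
                              role = c("original", "neighborhood", "fused",
                                       "integrated"),
                              omic_name = "integrated") {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) != ncol(values))
    stop("'values' must be a square numeric matrix")
  if (is.null(rownames(values)))
    stop("'values' must carry sample ids as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column sample ids must be identical")
  if (anyNA(values) || any(!is.finite(values)))
    stop("similarity matrix contains non-finite values")
  if (max(abs(values - t(values))) > 1e-10)
    stop("similarity matrix is not symmetric (tolerance 1e-10)")
  if (min(values) < -1e-12)
    stop("similarity matrix has negative entries")
  values[values < 0] <- 0
  if (role == "original") {
    if (max(abs(diag(values) - 1)) > 1e-10)
      stop("original similarity matrix must have a unit diagonal")
    if (max(values) > 1 + 1e-10)
      stop("original similarity matrix entries must be <= 1")
  }
  structure(
    list(values = values, role = role, omic_name = as.character(omic_name),
         sample_ids = rownames(values)),
    class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix role=%s omic=%s> %d x %d\n", x$role,
              x$omic_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a cluster assignment
#'
#' Per-sample integer cluster labels in `1..k`.
#'
#' @param labels Integer vector of cluster labels in `1..k`, one per sample.
#' @param sample_ids Character vector of unique sample ids, same length as
#'   `labels`. Defaults to the names of `labels`.
#' @param k Number of clusters; defaults to `max(labels)`.
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, sample_ids = names(labels),
                               k = max(labels)) {
  labels <- as.integer(labels)
  if (is.null(sample_ids))
    stop("'sample_ids' required (or supply named labels)")
  if (length(sample_ids) != length(labels))
    stop("'sample_ids' and 'labels' lengths differ")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in cluster assignment")
  if (anyNA(labels) || any(labels < 1L) || any(labels > k))
    stop("labels must be integers in 1..k with no missing values")
  structure(
    list(sample_ids = as.character(sample_ids), labels = labels,
         k = as.integer(k)),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d samples, k = %d; sizes: %s\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Construct a survival table
#'
#' Right-censored survival data: per-sample follow-up time and event
#' indicator (1 = event observed, 0 = censored).
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param time Nonnegative numeric follow-up times.
#' @param event Event indicators; 0/1, logical, or TRUE/FALSE.
#' @return An object of class `survival_table` (also a data.frame with
#'   columns `sample_id`, `time`, `event`).
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in survival table: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  time <- as.numeric(time)
  if (is.logical(event)) event <- as.integer(event)
  event <- as.numeric(event)
  n <- length(sample_ids)
  if (length(time) != n || length(event) != n)
    stop("'sample_ids', 'time' and 'event' must have equal length")
  bad_t <- which(is.na(time) | time < 0)
  if (length(bad_t))
    stop("negative or missing survival time in row(s): ",
         paste(bad_t, collapse = ", "))
  bad_e <- which(is.na(event) | !(event %in% c(0, 1)))
  if (length(bad_e))
    stop("event indicator outside {0,1} in row(s): ",
         paste(bad_e, collapse = ", "))
  structure(
    data.frame(sample_id = sample_ids, time = time, event = as.integer(event),
               stringsAsFactors = FALSE),
    class = c("survival_table", "data.frame"))
}
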
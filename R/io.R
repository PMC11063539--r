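#' Read an omic matrix from delimited text
#'
#' Reads a CSV/TSV matrix with one header row and one leading id column and
#' returns it in samples-by-features orientation. Non-numeric cells become
#' missing values.
#'
#' @param path Path to a comma- or tab-delimited text file.
#' @param orientation `"samples_in_rows"` (default) if file rows are samples,
#'   `"samples_in_columns"` if file rows are features.
#' @param omic_name Label for the layer.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return An [omics_matrix].
#' @export
read_omics_matrix <- function(path,
                              orientation = c("samples_in_rows",
                                              "samples_in_columns"),
                              omic_name = "omic", sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L || nrow(df) < 1L) stop("empty matrix in ", path)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated id(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "character"
  vals <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                  dimnames = list(ids, colnames(df)[-1L])))
  if (orientation == "samples_in_columns") vals <- t(vals)
  omics_matrix(vals, omic_name)
}

#' Write an omic matrix to CSV
#'
#' Inverse of [read_omics_matrix()]: samples in rows, one leading id column,
#' full precision.
#'
#' @param m An [omics_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(sample_id = m$sample_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix to CSV
#'
#' Square CSV with sample ids as both header and index column.
#'
#' @param a A [similarity_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(a, path) {
  stopifnot(inherits(a, "similarity_matrix"))
  df <- data.frame(sample_id = a$sample_ids, a$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from delimited text
#'
#' @param path Path to a CSV/TSV file.
#' @param id_col,time_col,event_col Column names (defaults `sample_id`,
#'   `time`, `event`). Event values may be 0/1 or TRUE/FALSE.
#' @param sep Field separator; auto-detected when `NULL`.
#' @return A [survival_table].
#' @export
read_survival_table <- function(path, id_col = "sample_id", time_col = "time",
                                event_col = "event", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, time_col, event_col))
    if (!col %in% colnames(df))
      stop("column '", col, "' not found in ", path)
  ev <- df[[event_col]]
  if (is.character(ev)) {
    ev_up <- toupper(trimws(ev))
    ev <- ifelse(ev_up %in% c("TRUE", "T", "1"), 1,
                 ifelse(ev_up %in% c("FALSE", "F", "0"), 0, NA))
  }
  survival_table(df[[id_col]], df[[time_col]], ev)
}

#' Filter features by missingness and zeros
#'
#' Drops every feature whose count of missing-or-exactly-zero entries
#' exceeds `max_bad_fraction` of the samples (strict inequality), then
#' imputes any remaining missing entries. Feature order is preserved.
#'
#' @param m An [omics_matrix].
#' @param max_bad_fraction Maximum tolerated fraction of bad (zero or
#'   missing) entries per feature; default 0.20.
#' @param impute How to fill missing entries that survive the filter:
#'   `"mean"` (feature-wise observed mean, default), `"zero"`, or `"fail"`
#'   to reject any remaining missingness.
#' @return A filtered [omics_matrix]; the number of dropped features is
#'   attached as attribute `n_dropped`.
#' @export
filter_features_by_missingness <- function(m, max_bad_fraction = 0.20,
                                           impute = c("mean", "zero", "fail")) {
  stopifnot(inherits(m, "omics_matrix"))
  impute <- match.arg(impute)
  if (max_bad_fraction < 0 || max_bad_fraction > 1)
    stop("'max_bad_fraction' must be in [0, 1]")
  vals <- m$values
  n <- nrow(vals)
  bad <- is.na(vals) | vals == 0
  keep <- colSums(bad) <= max_bad_fraction * n
  if (!any(keep))
    stop("all features of omic '", m$omic_name,
         "' dropped at missing/zero threshold ", max_bad_fraction)
  vals <- vals[, keep, drop = FALSE]
  if (anyNA(vals)) {
    if (impute == "fail")
      stop("missing values remain after filtering omic '", m$omic_name, "'")
    if (impute == "zero") {
      vals[is.na(vals)] <- 0
    } else {
      mu <- colMeans(vals, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      idx <- which(is.na(vals), arr.ind = TRUE)
      vals[idx] <- mu[idx[, 2L]]
    }
  }
  out <- omics_matrix(vals, m$omic_name)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Align omic layers (and survival data) to a common cohort
#'
#' Restricts every layer to the intersection of sample ids, in one canonical
#' shared order (lexicographic by id), so matrices across omics are
#' row-aligned by construction. Alignment is done before missingness
#' filtering so that missingness fractions refer to the analysis cohort.
#'
#' @param layers List of [omics_matrix] objects (>= 2).
#' @param surv Optional [survival_table]; restricted and reordered the same
#'   way.
#' @return A list with elements `layers` (aligned omics matrices),
#'   `survival` (aligned table or `NULL`) and `n_dropped` (samples dropped
#'   per input, named).
#' @export
align_cohort <- function(layers, surv = NULL) {
  if (!is.list(layers) || length(layers) < 2L)
    stop("need at least two omic layers")
  lapply(layers, function(l) stopifnot(inherits(l, "omics_matrix")))
  id_sets <- lapply(layers, function(l) l$sample_ids)
  if (!is.null(surv)) {
    stopifnot(inherits(surv, "survival_table"))
    id_sets <- c(id_sets, list(surv$sample_id))
  }
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L)
    stop("no samples shared across all inputs")
  common <- sort(common, method = "radix")
  dropped <- vapply(id_sets, function(ids) length(ids) - length(common),
                    integer(1))
  names(dropped) <- c(vapply(layers, function(l) l$omic_name, character(1)),
                      if (!is.null(surv)) "survival")
  out_layers <- lapply(layers, function(l)
    omics_matrix(l$values[common, , drop = FALSE], l$omic_name))
  out_surv <- NULL
  if (!is.null(surv)) {
    rows <- match(common, surv$sample_id)
    out_surv <- survival_table(surv$sample_id[rows], surv$time[rows],
                               surv$event[rows])
  }
  list(layers = out_layers, survival = out_surv, n_dropped = dropped)
}
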
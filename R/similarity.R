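#' Pairwise patient similarity from one omic layer
#'
#' Builds the patient-patient similarity matrix of an omic layer with a
#' Gaussian profile kernel on Euclidean distances between feature profiles:
#' `A[i, j] = exp(-alpha * d(i, j)^2)` where `d` is the Euclidean distance
#' between the profiles of patients `i` and `j`. The bandwidth `alpha`
#' regulates the decay of similarity with distance: for a fixed distance the
#' similarity is strictly decreasing in `alpha`. The kernel is the Gaussian
#' interaction profile kernel, whose standard form uses the squared norm;
#' an unsquared-distance variant is available for sensitivity analysis.
#'
#' The kernel is informative when profile distances are of order one; for
#' wide feature panels consider standardizing or rescaling features during
#' preprocessing so distances do not saturate the exponential.
#'
#' @param m An [omics_matrix] with no missing values (preprocessing
#'   complete).
#' @param alpha Positive kernel bandwidth; default 1.5.
#' @param squared Use the squared Euclidean distance in the exponent
#'   (default `TRUE`); `FALSE` uses the plain distance.
#' @return A [similarity_matrix] with `role = "original"`: symmetric,
#'   entries in (0, 1], unit diagonal.
#' @examples
#' x <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
#' a <- pairwise_similarity(omics_matrix(x, "mRNA"), alpha = 1.5)
#' @export
pairwise_similarity <- function(m, alpha = 1.5, squared = TRUE) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$values))
    stop("omic '", m$omic_name,
         "' contains missing values; run preprocessing first")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar")
  d <- as.matrix(stats::dist(m$values, method = "euclidean"))
  expo <- if (squared) d^2 else d
  a <- exp(-alpha * expo)
  a <- (a + t(a)) / 2  # absorb floating-point asymmetry of dist()
  diag(a) <- 1
  dimnames(a) <- list(m$sample_ids, m$sample_ids)
  similarity_matrix(a, role = "original", omic_name = m$omic_name)
}
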
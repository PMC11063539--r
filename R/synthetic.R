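#' Specify a synthetic multiomic cohort
#'
#' Describes a cohort with `K` planted patient groups whose signal may be
#' distributed across omic layers, optionally only partially: each omic
#' carries a `merge_map` collapsing the `K` groups into the groups that the
#' omic can actually distinguish, which enables complementary-signal
#' designs where no single layer resolves the full structure.
#'
#' Informative features are drawn from group-conditional Gaussians whose
#' group means are separated by `separation` within-group standard
#' deviations (expected pairwise mean difference per informative feature);
#' the remaining features are pure noise. Each omic is scaled so that the
#' typical distance between two same-group patient profiles is of order
#' one, the regime in which the default similarity-kernel bandwidth
#' (`alpha = 1.5`) discriminates between close and distant patients.
#'
#' @param n_per_cluster Integer vector of group sizes (length `K`).
#' @param omics List of per-omic specs as built by [omic_spec()]; default is
#'   three fully informative layers named mRNA, miRNA, methylation.
#' @param missing_fraction Fraction of entries set to missing uniformly at
#'   random in every omic (default 0).
#' @param seed Integer master seed; each omic uses a deterministic
#'   sub-stream, so adding an omic does not perturb the others.
#' @return An object of class `simulation_spec`.
#' @seealso [simulation_preset()] for ready-made designs.
#' @export
simulation_spec <- function(n_per_cluster = c(20L, 20L, 20L), omics = NULL,
                            missing_fraction = 0, seed = 0L) {
  n_per_cluster <- as.integer(n_per_cluster)
  if (any(n_per_cluster < 1L)) stop("all group sizes must be positive")
  k <- length(n_per_cluster)
  if (k < 2L) stop("need at least two planted groups")
  if (is.null(omics))
    omics <- lapply(c("mRNA", "miRNA", "methylation"), omic_spec)
  omics <- lapply(omics, function(o) {
    stopifnot(inherits(o, "omic_spec"))
    if (is.null(o$merge_map)) o$merge_map <- seq_len(k)
    if (length(o$merge_map) != k)
      stop("merge_map of omic '", o$omic_name, "' must have length K = ", k)
    mm <- as.integer(o$merge_map)
    if (!setequal(mm, seq_len(max(mm))))
      stop("merge_map of omic '", o$omic_name,
           "' must use consecutive group ids 1..G")
    o$merge_map <- mm
    o
  })
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("'missing_fraction' must be in [0, 1)")
  structure(
    list(n_per_cluster = n_per_cluster, k = k, omics = omics,
         missing_fraction = missing_fraction, seed = as.integer(seed)),
    class = "simulation_spec")
}

#' Per-omic settings of a synthetic cohort
#'
#' @param omic_name Layer label.
#' @param n_features Total features (default 20).
#' @param n_informative Features carrying group signal (default 10).
#' @param separation Between-group mean separation of informative features,
#'   in units of within-group standard deviation (default 6;
#'   0 = pure noise).
#' @param merge_map Optional integer vector of length `K` mapping each
#'   planted group to the merged group the omic can distinguish
#'   (`NULL` = all groups distinguishable).
#' @return An object of class `omic_spec`.
#' @export
omic_spec <- function(omic_name, n_features = 20L, n_informative = 10L,
                      separation = 6, merge_map = NULL) {
  if (separation < 0) stop("'separation' must be nonnegative")
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  if (n_features < 1L || n_informative < 0L || n_informative > n_features)
    stop("need 0 <= n_informative <= n_features with n_features >= 1")
  structure(
    list(omic_name = as.character(omic_name), n_features = n_features,
         n_informative = n_informative, separation = separation,
         merge_map = merge_map),
    class = "omic_spec")
}

#' Ready-made simulation designs
#'
#' `"strong"`: every omic distinguishes all three groups (separation 6).
#' `"complementary"`: omic 1 only separates groups \{1,2\} from \{3\},
#' omic 2 only separates \{1\} from \{2,3\}, omic 3 is pure noise, so no
#' single layer resolves all three groups but their integration does.
#' `"null"`: no omic carries any group signal.
#'
#' @param design One of `"strong"`, `"complementary"`, `"null"`.
#' @param n_per_cluster Group sizes (length 3; default 20 each).
#' @param separation Signal strength for informative layers (default 6).
#' @param seed Integer seed.
#' @return A [simulation_spec].
#' @export
simulation_preset <- function(design = c("strong", "complementary", "null"),
                              n_per_cluster = c(20L, 20L, 20L),
                              separation = 6, seed = 0L) {
  design <- match.arg(design)
  stopifnot(length(n_per_cluster) == 3L)
  omics <- switch(design,
    strong = list(
      omic_spec("mRNA", separation = separation),
      omic_spec("miRNA", separation = separation),
      omic_spec("methylation", separation = separation)),
    complementary = list(
      omic_spec("mRNA", separation = separation,
                merge_map = c(1L, 1L, 2L)),
      omic_spec("miRNA", separation = separation,
                merge_map = c(1L, 2L, 2L)),
      omic_spec("methylation", separation = 0)),
    null = list(
      omic_spec("mRNA", separation = 0),
      omic_spec("miRNA", separation = 0),
      omic_spec("methylation", separation = 0)))
  simulation_spec(n_per_cluster = n_per_cluster, omics = omics, seed = seed)
}

#' Generate a synthetic multiomic cohort
#'
#' Draws the omic layers described by a [simulation_spec]: informative
#' features from group-conditional Gaussians (group means separated
#' according to the omic's merged-group view), noise features from a
#' standard Gaussian, optional uniform missingness, shared sample ids
#' across layers. Deterministic for a fixed spec and seed.
#'
#' @param spec A [simulation_spec].
#' @return List with `layers` (list of [omics_matrix]) and `truth`
#'   (the planted [cluster_assignment]).
#' @export
generate_multiomic <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- sum(spec$n_per_cluster)
  lab <- rep(seq_len(spec$k), spec$n_per_cluster)
  ids <- sprintf("S%04d", seq_len(n))
  layers <- vector("list", length(spec$omics))
  for (o in seq_along(spec$omics)) {
    os <- spec$omics[[o]]
    x <- withr::with_seed(sub_seed(spec$seed, o), {
      f <- os$n_features
      xo <- matrix(stats::rnorm(n * f), n, f)
      if (os$n_informative > 0L && os$separation > 0) {
        g <- max(os$merge_map)
        mu <- matrix(stats::rnorm(g * os$n_informative,
                                  sd = os$separation / sqrt(2)),
                     g, os$n_informative)
        inf <- seq_len(os$n_informative)
        xo[, inf] <- xo[, inf] + mu[os$merge_map[lab], , drop = FALSE]
      }
      # put typical same-group profile distances at order one
      xo <- xo / sqrt(2 * f)
      if (spec$missing_fraction > 0) {
        n_missing <- round(spec$missing_fraction * length(xo))
        xo[sample.int(length(xo), n_missing)] <- NA_real_
      }
      xo
    })
    dimnames(x) <- list(ids, paste0(os$omic_name, "_f",
                                    seq_len(os$n_features)))
    layers[[o]] <- omics_matrix(x, os$omic_name)
  }
  list(layers = layers,
       truth = cluster_assignment(lab, sample_ids = ids, k = spec$k))
}

#' Generate per-group exponential survival with right censoring
#'
#' Event times are exponential with a per-group hazard; censoring times are
#' independent exponentials whose rate is calibrated per group so that the
#' marginal probability of censoring equals `censor_rate` exactly
#' (`rate_cens = hazard * censor_rate / (1 - censor_rate)`).
#'
#' @param labels A [cluster_assignment] (or label vector in `1..K`).
#' @param hazards Positive per-group hazard rates (length `K`).
#' @param censor_rate Target marginal censoring fraction in \[0, 1);
#'   0 disables censoring.
#' @param seed Integer seed.
#' @return A [survival_table].
#' @export
generate_survival <- function(labels, hazards, censor_rate = 0, seed = 0L) {
  lab <- label_values(labels)
  ids <- if (inherits(labels, "cluster_assignment")) labels$sample_ids
         else sprintf("S%04d", seq_along(lab))
  k <- max(lab)
  hazards <- as.numeric(hazards)
  if (length(hazards) != k || any(!is.finite(hazards)) || any(hazards <= 0))
    stop("'hazards' must be ", k, " positive rates")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)")
  withr::with_seed(as.integer(seed), {
    t_event <- stats::rexp(length(lab), rate = hazards[lab])
    if (censor_rate > 0) {
      c_rate <- hazards[lab] * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(length(lab), rate = c_rate)
      survival_table(ids, pmin(t_event, t_cens),
                     as.integer(t_event <= t_cens))
    } else {
      survival_table(ids, t_event, rep(1L, length(lab)))
    }
  })
}
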
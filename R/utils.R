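# internal helpers

# coerce a similarity_matrix or plain matrix to its numeric matrix
sim_values <- function(a) {
  if (inherits(a, "similarity_matrix")) a$values
  else if (is.matrix(a)) a
  else stop("expected a similarity_matrix or a matrix")
}

# coerce a cluster_assignment or plain vector to integer labels
label_values <- function(ca) {
  if (inherits(ca, "cluster_assignment")) ca$labels
  else as.integer(as.factor(ca))
}

# derive a reproducible sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, ...) {
  offsets <- c(...)
  as.integer((as.numeric(seed) + sum(offsets * 100003)) %% .Machine$integer.max)
}

# seeded Lloyd k-means; Hartigan-Wong errors out on degenerate embeddings
# with many duplicated rows
seeded_kmeans <- function(x, k, seed, nstart = 20L) {
  withr::with_seed(as.integer(seed), {
    suppressWarnings(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = 200L,
                    algorithm = "Lloyd"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
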
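# Independent brute-force oracles used across tests. These deliberately
# re-derive every quantity with scalar loops / closed forms, sharing no code
# with the package implementation.

# all set partitions of n elements as label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1L))
      recurse(c(labels, v), max(next_max, v))
  }
  recurse(integer(0), 0L)
  out
}

# pair-counting ARI and FM from the four pair categories
pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  ari_num <- 2 * (n11 * n00 - n10 * n01)
  ari_den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  fm <- if (n11 + n10 == 0 || n11 + n01 == 0) 0
        else n11 / sqrt((n11 + n10) * (n11 + n01))
  list(ari = if (ari_den == 0) 1 else ari_num / ari_den, fm = fm)
}

# scalar per-pair Gaussian kernel
kernel_oracle <- function(x, alpha) {
  n <- nrow(x)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- sum((x[i, ] - x[j, ])^2)
    a[i, j] <- exp(-alpha * d2)
  }
  a
}

# scalar evaluation of the neighborhood formula with its own D/eta
neighborhood_oracle <- function(a_vals, lab, beta, mu) {
  k <- max(lab)
  n <- nrow(a_vals)
  cent <- matrix(0, k, ncol(a_vals))
  for (c in seq_len(k))
    cent[c, ] <- colMeans(a_vals[lab == c, , drop = FALSE])
  md <- numeric(k)
  for (c in seq_len(k)) {
    members <- which(lab == c)
    md[c] <- mean(vapply(members, function(q)
      sqrt(sum((a_vals[q, ] - cent[c, ])^2)), numeric(1)))
  }
  abar <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ci <- lab[i]; cj <- lab[j]
    cd <- sqrt(sum((cent[ci, ] - cent[cj, ])^2))
    eta <- (md[ci] + md[cj] + cd) / 3
    d_val <- exp(beta * cd^2 / (eta + 1))
    abar[i, j] <- 2 * a_vals[i, j]^2 / (d_val * (mu + md[ci] + md[cj]))
  }
  abar
}

# entrywise triple-product sum over the other omics for one target omic
fusion_oracle <- function(a_vals_list, s, target) {
  n <- nrow(s)
  m <- matrix(0, n, n)
  for (o2 in seq_along(a_vals_list)) {
    if (o2 == target) next
    a <- a_vals_list[[o2]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (p in seq_len(n)) for (q in seq_len(n))
        acc <- acc + s[i, p] * a[p, q] * s[j, q]
      m[i, j] <- m[i, j] + acc
    }
  }
  m
}

# per-point a/b silhouette
silhouette_oracle <- function(x, lab) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(c)
      mean(d[i, lab == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# wrap a plain numeric matrix as an omics_matrix with generated ids
as_omics <- function(x, omic_name = "omic") {
  dimnames(x) <- list(sprintf("s%03d", seq_len(nrow(x))),
                      sprintf("f%03d", seq_len(ncol(x))))
  omics_matrix(x, omic_name)
}

# wrap a matrix that already carries its own dimnames
as_omics_keepnames <- function(x, omic_name = "omic") omics_matrix(x, omic_name)

# wrap a plain symmetric matrix as a similarity_matrix
as_sim <- function(x, role = "original") {
  dimnames(x) <- list(sprintf("s%03d", seq_len(nrow(x))),
                      sprintf("s%03d", seq_len(nrow(x))))
  similarity_matrix(x, role = role)
}

# block-structured affinity matrix with planted groups
block_affinity <- function(sizes, within = 0.9, between = 0.01) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  a <- matrix(between, n, n)
  for (c in seq_along(sizes)) a[lab == c, lab == c] <- within
  diag(a) <- 1
  list(a = as_sim(a), lab = lab)
}
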
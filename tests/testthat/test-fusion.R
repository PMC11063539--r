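random_sym <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n, 0.05, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
}

test_that("fusion config validates its parameters", {
  expect_error(fusion_config(), "'k'")
  expect_error(fusion_config(k = 1), ">= 2")
  expect_error(fusion_config(k = 3, alpha = -1), "positive")
  expect_error(fusion_config(k = 3, mu = 0), "positive")
  expect_error(fusion_config(k = 3, iterations = 0), ">= 1")
  cfg <- fusion_config(k = 3)
  expect_equal(cfg$alpha, 1.5)
  expect_equal(cfg$mu, 1)
  expect_equal(cfg$beta, 0.5)
  expect_equal(cfg$iterations, 7L)
})

test_that("raw fusion step is the literal triple-product sum", {
  a_list <- lapply(1:3, function(o) as_sim(random_sym(3, o)))
  abar_list <- lapply(4:6, function(o) as_sim(random_sym(3, o) / 2,
                                              role = "neighborhood"))
  stepped <- fusion_step(a_list, abar_list, operator = "raw",
                         rescale = FALSE)
  avals <- lapply(a_list, function(a) a$values)
  for (o in 1:3) {
    s <- abar_list[[o]]$values
    expected <- fusion_oracle(avals, s, o)
    expected <- (expected + t(expected)) / 2
    expect_equal(stepped[[o]]$values, expected, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("self-weighted fusion step matches its entrywise oracle", {
  a_list <- lapply(1:3, function(o) as_sim(random_sym(4, 10 + o)))
  abar_list <- lapply(1:3, function(o) as_sim(random_sym(4, 20 + o) / 2,
                                              role = "neighborhood"))
  stepped <- fusion_step(a_list, abar_list, operator = "self_weighted",
                         smoothing_weight = 0.2, rescale = FALSE)
  avals <- lapply(a_list, function(a) a$values)
  for (o in 1:3) {
    ab <- abar_list[[o]]$values
    s <- 0.8 * diag(4) + 0.2 * ab / rowSums(ab)
    expected <- fusion_oracle(avals, s, o)
    expected <- (expected + t(expected)) / 2
    expect_equal(stepped[[o]]$values, expected, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("identity message operators reduce the update to a sum of omics", {
  a_list <- lapply(1:3, function(o) as_sim(random_sym(4, 30 + o)))
  id_bar <- as_sim(diag(4), role = "neighborhood")
  stepped <- fusion_step(a_list, list(id_bar, id_bar, id_bar),
                         operator = "raw", rescale = FALSE)
  expect_equal(stepped[[1]]$values,
               a_list[[2]]$values + a_list[[3]]$values, ignore_attr = TRUE)
})

test_that("fusion preserves symmetry, nonnegativity, finiteness over 7 rounds", {
  for (operator in c("self_weighted", "raw")) {
    a_list <- lapply(1:3, function(o) as_sim(random_sym(6, 40 + o)))
    cur <- a_list
    for (it in 1:7) {
      abar_list <- lapply(cur, function(a) {
        ca <- spectral_clusters(a, 2, seed = it)
        g <- cluster_geometry(a, ca)
        neighborhood_matrix(a, g, ca)
      })
      cur <- fusion_step(cur, abar_list, operator = operator, rescale = TRUE)
      for (m in cur) {
        expect_true(all(is.finite(m$values)))
        expect_true(all(m$values >= 0))
        expect_equal(m$values, t(m$values))
        expect_lte(max(m$values), 1)
      }
    }
  }
})

test_that("fusion step rejects malformed input", {
  a_list <- lapply(1:2, function(o) as_sim(random_sym(3, o)))
  expect_error(fusion_step(a_list[1], a_list[1]), "at least two")
  b <- as_sim(random_sym(4, 9))
  expect_error(fusion_step(list(a_list[[1]], b), a_list), "identical size")
})

test_that("integration is the elementwise mean and validates sizes", {
  m <- random_sym(4, 50)
  ints <- integrate_similarity(list(as_sim(m), as_sim(2 * m, role = "fused"),
                                    as_sim(3 * m, role = "fused")))
  expect_equal(ints$values, 2 * m, ignore_attr = TRUE)
  expect_identical(ints$role, "integrated")

  same <- integrate_similarity(list(as_sim(m), as_sim(m)))
  expect_equal(same$values, m, ignore_attr = TRUE)  # two-omic case
  expect_error(integrate_similarity(list(as_sim(m))), "at least two")
})

test_that("final K-means recovers perfect blocks and is deterministic", {
  ba <- block_affinity(c(8, 8), within = 0.9, between = 0.02)
  ca <- final_kmeans(ba$a, k = 2, seed = 3)
  expect_equal(adjusted_rand_index(ca$labels, ba$lab), 1)
  ca2 <- final_kmeans(ba$a, k = 2, seed = 3)
  expect_identical(ca$labels, ca2$labels)
  expect_error(final_kmeans(ba$a, k = 1, seed = 1), "2 <= k")
  expect_error(final_kmeans(ba$a, k = 16, seed = 1), "2 <= k")
})

test_that("run_icluf validates input and supports a single iteration", {
  sim <- generate_multiomic(simulation_preset("strong", seed = 4))
  expect_error(run_icluf(sim$layers[1], fusion_config(k = 3)),
               "at least two")
  expect_error(fusion_config(k = 3, iterations = 0), ">= 1")
  res1 <- run_icluf(sim$layers, fusion_config(k = 3, iterations = 1,
                                              seed = 4))
  expect_length(res1$per_iteration_silhouette, 1)
  expect_equal(adjusted_rand_index(res1$assignment, sim$truth), 1)
})

test_that("permuting patients permutes the result equivalently", {
  sim <- generate_multiomic(simulation_preset("strong", seed = 5))
  res <- run_icluf(sim$layers, fusion_config(k = 3, seed = 5))
  withr::with_seed(5, perm <- sample(length(sim$truth$labels)))
  perm_layers <- lapply(sim$layers, function(l)
    omics_matrix(l$values[perm, , drop = FALSE], l$omic_name))
  # re-sort into the canonical order expected by run_icluf inputs:
  # permutation equivariance is asserted through the sample-id keyed labels
  res_p <- run_icluf(perm_layers, fusion_config(k = 3, seed = 5))
  back <- match(res$assignment$sample_ids, res_p$assignment$sample_ids)
  expect_equal(adjusted_rand_index(res$assignment$labels,
                                   res_p$assignment$labels[back]), 1)
})

test_that("identical layers fuse to the single-layer structure", {
  sim <- generate_multiomic(simulation_preset("strong", seed = 6))
  l1 <- sim$layers[[1]]
  twin <- omics_matrix(l1$values, "copy")
  res <- run_icluf(list(l1, twin), fusion_config(k = 3, seed = 6))
  # both per-omic matrices stay identical, and the integrated matrix
  # equals each of them
  expect_equal(res$final_per_omic[[1]]$values, res$final_per_omic[[2]]$values)
  expect_equal(res$integrated$values, res$final_per_omic[[1]]$values)
  expect_equal(adjusted_rand_index(res$assignment, sim$truth), 1)
})

test_that("silhouette trace is weakly increasing on separable data", {
  sim <- generate_multiomic(simulation_preset("strong", seed = 7))
  res <- run_icluf(sim$layers, fusion_config(k = 3, seed = 7))
  expect_true(all(diff(res$per_iteration_silhouette) > -0.02))
})
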
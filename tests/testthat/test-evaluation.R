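test_that("ARI and FM match exhaustive pair counting on small partitions", {
  # spot examples
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  o <- pair_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), o$ari)
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 2, 1, 2)), o$fm)
  # all singletons vs one cluster
  o2 <- pair_oracle(1:5, rep(1, 5))
  expect_equal(adjusted_rand_index(1:5, rep(1, 5)), o2$ari)

  # random partition pairs at n = 5..8 against the pair-counting oracle
  withr::with_seed(13, {
    for (rep in 1:25) {
      n <- sample(5:8, 1)
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      o <- pair_oracle(a, b)
      expect_equal(adjusted_rand_index(a, b), o$ari, tolerance = 1e-12)
      expect_equal(fowlkes_mallows(a, b), o$fm, tolerance = 1e-12)
    }
  })
})

test_that("ARI and FM are symmetric and label-permutation invariant", {
  withr::with_seed(21, {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(fowlkes_mallows(a, b), fowlkes_mallows(b, a))
  relabel <- c(3, 1, 2)[a]
  expect_equal(adjusted_rand_index(relabel, b), adjusted_rand_index(a, b))
  expect_equal(fowlkes_mallows(relabel, b), fowlkes_mallows(a, b))
})

test_that("metric inputs must cover the same samples", {
  ca1 <- cluster_assignment(c(1, 2), sample_ids = c("a", "b"), k = 2)
  ca2 <- cluster_assignment(c(1, 2), sample_ids = c("a", "c"), k = 2)
  expect_error(adjusted_rand_index(ca1, ca2), "different samples")
  expect_error(adjusted_rand_index(c(1, 2), c(1, 2, 1)), "different numbers")
})

test_that("FM of independent random partitions sits at its chance level", {
  # E[FM] ~ sqrt(Pa * Pb) where Pa, Pb are the probabilities that a random
  # pair is co-clustered under each partition's fixed sizes
  n <- 200
  sizes_a <- c(50, 50, 100)
  sizes_b <- c(120, 80)
  base_a <- rep(1:3, sizes_a)
  base_b <- rep(1:2, sizes_b)
  pa <- sum(choose(sizes_a, 2)) / choose(n, 2)
  pb <- sum(choose(sizes_b, 2)) / choose(n, 2)
  withr::with_seed(99, {
    fms <- replicate(100, fowlkes_mallows(sample(base_a), sample(base_b)))
  })
  se <- sd(fms) / sqrt(length(fms))
  expect_lt(abs(mean(fms) - sqrt(pa * pb)), 3 * se + 1e-3)
})

test_that("silhouette matches the per-point brute force and its range", {
  x <- rbind(c(0, 0), c(0.3, 0), c(5, 5), c(5.4, 5))
  lab <- c(1, 1, 2, 2)
  a <- as_sim({m <- exp(-as.matrix(dist(x))^2); diag(m) <- 1; m})
  # hand-set coordinates: compare against direct a(i)/b(i) computation
  expect_equal(silhouette_score(x, lab), silhouette_oracle(x, lab),
               tolerance = 1e-12)
  withr::with_seed(31, {
    y <- matrix(rnorm(40), 10, 4)
    labr <- sample(1:3, 10, replace = TRUE)
  })
  labr[1:3] <- 1:3  # ensure all clusters present
  s <- silhouette_score(y, labr)
  expect_equal(s, silhouette_oracle(y, labr), tolerance = 1e-12)
  expect_gte(s, -1)
  expect_lte(s, 1)
})

test_that("two far identical-row blocks approach silhouette 1", {
  vals <- rbind(matrix(rep(c(1, 1, 0, 0), 3), 3, byrow = TRUE),
                matrix(rep(c(0, 0, 1, 1), 3), 3, byrow = TRUE))
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(silhouette_score(vals, lab), 1, tolerance = 1e-6)
  expect_error(silhouette_score(vals, rep(1, 6)), "single cluster")
})

test_that("planted clustering scores higher silhouette than random labels", {
  better <- 0
  for (seed in 1:20) {
    sim <- generate_multiomic(simulation_preset("strong", seed = seed,
                                                n_per_cluster = c(8, 8, 8)))
    a <- pairwise_similarity(sim$layers[[1]])
    s_true <- silhouette_score(a, sim$truth)
    rand_lab <- withr::with_seed(seed, sample(sim$truth$labels))
    s_rand <- silhouette_score(a, cluster_assignment(
      rand_lab, sample_ids = sim$truth$sample_ids, k = 3))
    if (s_true > s_rand) better <- better + 1
  }
  expect_equal(better, 20)
})

test_that("log-rank matches survival::survdiff on a censored example", {
  surv <- survival_table(sprintf("s%02d", 1:10),
                         time = c(3, 5, 7, 2, 18, 16, 2, 9, 16, 5),
                         event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1))
  lab <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  lr <- logrank_test(surv, lab)
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ lab)
  expect_equal(lr$stat, sd$chisq, tolerance = 1e-6)
  expect_equal(lr$p, 1 - pchisq(sd$chisq, 1), tolerance = 1e-6)
  expect_identical(lr$df, 1L)

  # three groups with ties
  withr::with_seed(41, {
    t3 <- round(rexp(30, 0.3), 1) + 0.1
    e3 <- rbinom(30, 1, 0.8)
    g3 <- rep(1:3, each = 10)
  })
  lr3 <- logrank_test(survival_table(sprintf("t%02d", 1:30), t3, e3), g3)
  sd3 <- survival::survdiff(survival::Surv(t3, e3) ~ g3)
  expect_equal(lr3$stat, sd3$chisq, tolerance = 1e-6)
  expect_identical(lr3$df, 2L)
})

test_that("identical groups give statistic 0 and p 1", {
  tt <- c(1, 2, 3, 4, 5)
  surv <- survival_table(sprintf("s%02d", 1:10), c(tt, tt),
                         c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1))
  lr <- logrank_test(surv, rep(1:2, each = 5))
  expect_equal(lr$stat, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("log-rank is invariant to time rescaling and validates input", {
  withr::with_seed(43, {
    tt <- rexp(40, 0.5)
    ev <- rbinom(40, 1, 0.7)
    g <- rep(1:2, each = 20)
  })
  s1 <- survival_table(sprintf("s%02d", 1:40), tt, ev)
  s2 <- survival_table(sprintf("s%02d", 1:40), 365 * tt, ev)
  expect_equal(logrank_test(s1, g)$stat, logrank_test(s2, g)$stat,
               tolerance = 1e-10)
  expect_error(logrank_test(s1, rep(1, 40)), "two nonempty groups")
  s0 <- survival_table(c("a", "b"), c(1, 2), c(0, 0))
  expect_error(logrank_test(s0, c(1, 2)), "no events")
})

test_that("Kaplan-Meier estimates match the product-limit hand computation", {
  # one group, events at t = 1, 2 among n = 2: survival 0.5 then 0
  surv <- survival_table(c("a", "b", "c"), c(1, 2, 5), c(1, 1, 1))
  km <- km_curves(surv, c(1, 1, 2))
  g1 <- km[km$group == "1", ]
  expect_equal(g1$survival, c(0.5, 0))
  expect_equal(g1$n_at_risk, c(2, 1))

  # censoring: n=4, event at 1, censor at 2, event at 3, censor at 4
  s2 <- survival_table(sprintf("x%d", 1:4), 1:4, c(1, 0, 1, 0))
  km2 <- km_curves(s2, rep(1, 4))
  surv_at <- km2$survival[km2$n_events == 1]
  expect_equal(surv_at, c(3 / 4, 3 / 4 * 1 / 2))

  # all-censored group stays at 1
  s3 <- survival_table(c("p", "q", "r", "t"), c(2, 3, 1, 4), c(0, 0, 1, 1))
  km3 <- km_curves(s3, c(1, 1, 2, 2))
  expect_true(all(km3$survival[km3$group == "1"] == 1))
  # within-group sample order irrelevant
  s3b <- survival_table(c("q", "p", "r", "t"), c(3, 2, 1, 4), c(0, 0, 1, 1))
  km3b <- km_curves(s3b, c(1, 1, 2, 2))
  expect_equal(km3[order(km3$group, km3$time), ],
               km3b[order(km3b$group, km3b$time), ], ignore_attr = TRUE)
})

test_that("cluster-subset survival runs one log-rank per combination", {
  withr::with_seed(53, {
    lab <- rep(1:5, each = 12)
    ids <- sprintf("s%03d", seq_along(lab))
    surv <- generate_survival(cluster_assignment(lab, ids, 5),
                              hazards = c(0.2, 0.4, 0.6, 0.8, 1),
                              censor_rate = 0.2, seed = 53)
  })
  ca <- cluster_assignment(lab, ids, 5)
  res <- cluster_subset_survival(surv, ca, subset_sizes = c(2, 3, 4))
  expect_equal(sum(res$subset_size == 2), 10)
  expect_equal(sum(res$subset_size == 3), 10)
  expect_equal(sum(res$subset_size == 4), 5)
  expect_true(all(res$df == res$subset_size - 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # pairwise test equals a direct two-group log-rank on that restriction
  members <- lab %in% c(1, 3)
  direct <- logrank_test(surv[match(ids[members], surv$sample_id), ],
                         cluster_assignment(match(lab[members], c(1, 3)),
                                            ids[members], 2))
  expect_equal(res$p[res$clusters == "1+3"], direct$p, tolerance = 1e-12)

  expect_error(cluster_subset_survival(surv, ca, subset_sizes = 5), "2..")
  res_bh <- cluster_subset_survival(surv, ca, 2, adjust = TRUE)
  expect_true(all(res_bh$p_bh >= res_bh$p - 1e-15))
})
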
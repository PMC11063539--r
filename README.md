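# iCluF — iterative cluster fusion for multiomic patient stratification

Heterogeneous diseases hide molecular subtypes that no single omic layer
reveals on its own. `iCluF` stratifies a patient cohort from two or more
omic matrices (e.g. mRNA expression, miRNA expression, DNA methylation
measured on the same samples) by fusing patient-similarity networks:

1. **Similarity** — per omic *o*, a Gaussian profile kernel on Euclidean
   distances, `A^o_ij = exp(−α‖p_i − p_j‖²)` (default `α = 1.5`).
2. **Neighborhood** — each omic's matrix is spectrally clustered at the
   user's `K` and reweighted by its cluster geometry,
   `Ābar^o_ij = 2(A^o_ij)² / [D(c_i,c_j)·(µ + d̄_ci + d̄_cj)]`, where `D`
   grows exponentially with normalized inter-centroid distance (gain `β`,
   default 0.5) and `µ = 1` guards the denominator. Pairs inside tight,
   well-separated clusters are boosted.
3. **Fusion** — iterative cross-omic message passing,
   `A^o ← Σ_{o'≠o} S^o A^{o'} S^oᵀ` with a self-weighted row-normalized
   message operator built from `Ābar^o`, symmetrized and rescaled each of
   7 (default) iterations; then the per-omic matrices are averaged and
   K-means on the integrated matrix yields the subtypes.

The package also provides the matching evaluation toolkit (silhouette,
adjusted Rand index, Fowlkes–Mallows, multi-group log-rank test and
Kaplan–Meier export, cluster-subset survival comparisons), a
random-forest Gini-importance analysis of per-omic contributions, a
synthetic multiomic cohort generator with planted (possibly
complementary) subtype signal and censored survival, and a command-line
interface (`inst/cli/icluf.R`) with `run`, `evaluate`, `importance` and
`simulate` subcommands.

## Worked example

A cohort of 60 patients in three planted subtypes with *complementary*
signal — mRNA only separates groups {1,2} from {3}, miRNA only {1} from
{2,3}, methylation is pure noise — so no single layer can resolve all
three groups:

```r
library(iCluF)

sim <- generate_multiomic(simulation_preset("complementary", seed = 7))
res <- run_icluf(sim$layers, fusion_config(k = 3, seed = 7))
res
#> <fusion_result> 60 samples, k = 3, 7 iterations
#> cluster sizes: 20, 20, 20
#> silhouette trace: 0.179 0.213 0.260 0.313 0.366 0.413 0.449

adjusted_rand_index(res$assignment, sim$truth)
#> [1] 1

surv <- generate_survival(sim$truth, hazards = c(0.2, 0.6, 1.2),
                          censor_rate = 0.2, seed = 7)
lr <- logrank_test(surv, res$assignment)
sprintf("chi2 = %.2f on %d df, p = %.2g", lr$stat, lr$df, lr$p)
#> [1] "chi2 = 22.71 on 2 df, p = 1.2e-05"
```

The silhouette trace rises monotonically over the seven fusion
iterations as the clusters consolidate. The fused partition recovers the
planted subtypes exactly (ARI = 1) and separates their survival curves
(hazards 0.2/0.6/1.2, log-rank p ≈ 1e-05), while the best single-omic
spectral clustering only reaches ARI ≈ 0.45:

```r
sapply(sim$layers, function(l)
  adjusted_rand_index(spectral_clusters(pairwise_similarity(l), 3, seed = 7),
                      sim$truth$labels))
#> [1] 0.453 0.432 0.042
```

Which layer drove the subtypes is quantified by
`gini_importance()` + `omic_contribution()` (top-25% Gini sums, min–max
normalized across omics).

See `vignettes/icluf-methods.Rmd` for the model, every tunable
parameter, and the reasoning behind the numerically delicate design
choices.

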
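Package: iCluF
Title: Iterative Cluster Fusion for Multiomic Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised stratification of a patient cohort from two or more
    omic layers (e.g. mRNA expression, miRNA expression, DNA methylation)
    measured on the same samples. Per-omic patient-patient similarity matrices
    built with a Gaussian profile kernel are iteratively refined by
    cluster-geometry-aware neighborhood matrices and cross-omic message
    passing, then averaged into one integrated similarity matrix that is
    clustered into subtypes. Includes cluster-quality metrics (silhouette,
    adjusted Rand index, Fowlkes-Mallows), multi-group log-rank survival
    comparisons with Kaplan-Meier export, random-forest Gini-importance
    analysis of per-omic contributions, and a synthetic multiomic cohort
    generator with planted subtypes and matched survival for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    survival,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
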
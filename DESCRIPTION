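Package: pwsc
Title: Patient-Aware Differential Expression and Cell-Type Annotation for
    Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Donor-aware, distribution-free differential expression for
    single-cell RNA-seq cohorts: per-gene pairwise patient-versus-control
    Wilcoxon rank-biserial scores, the median pairwise score as test
    statistic, and an exact permutation null over donor-group
    reassignments. Includes the negative-binomial/log-normal simulation
    benchmark used to calibrate the test (with an edgeR comparison arm),
    a gene-set group-separation statistic ("gene set distance") on
    donor-level pseudobulk profiles, reference-signature cell-type
    annotation by multiple regression (GenSigPro) and by iterative
    Spearman correlation with bootstrap uncertainty, gradient-boosting
    consolidation of multiple annotations with grouped cross-validation,
    marker-gene identification, quality control and normalization for
    sparse count matrices, and small closed-form assay metrics for flow
    cytometry (FMO-referenced effect size) and extracellular-flux (OCR)
    measurements. Seeded synthetic-data generators reproduce the
    statistical structure the methods assume, so the full workflow runs
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
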
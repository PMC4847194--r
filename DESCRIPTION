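Package: micropls
Title: Compositionally Robust Multilevel Sparse PLS and Association
    Networks for Longitudinal Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links longitudinal gut-microbiome compositions to host
    metabolic phenotypes under antibiotic and dietary perturbation.
    Provides centered log-ratio transforms and prevalence filtering for
    compositional count tables, a two-factor within-subject variance
    decomposition for repeated-measures designs, L1-penalized (sparse)
    partial least squares regression with stability-based (StARS) model
    selection and bootstrap/permutation significance, Gaussian-mixture
    clustering of latent scores, per-cluster microbial association
    network inference by neighborhood selection, graphlet-based network
    comparison and attack-robustness analysis, microbiota-by-age
    maturity scoring, random-forest disease classification, and host
    metabolic phenotype scoring (HOMA-IR, insulin-resistance and NAFLD
    flags). Includes a synthetic longitudinal cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    mclust,
    randomForest,
    igraph,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
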
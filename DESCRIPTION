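Package: gbmsurv
Title: Survival-Class Prediction in Glioblastoma from Preoperative
    Connectomics and Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies glioblastoma patients into three overall-survival
    groups (<1 year, 1-2 years, >2 years) from preoperative imaging features:
    resting-state network functional connectivity summarized by distance
    correlation over 15 canonical networks (120 within/between-network
    similarities), contralesional cortical thickness over 34 Desikan-Killiany
    parcels, age and sex.  Functional-connectivity features are compressed by a
    single-hidden-layer autoencoder with sparse-unit pruning; a small
    feedforward neural network is trained under nested stratified
    cross-validation with a global holdout; permutation feature importance is
    back-attributed to raw network pairs, averaged per network and projected
    onto voxelwise network probability maps.  A synthetic-cohort generator
    emulating the study's data structure makes every stage testable without
    patient data, and Kaplan-Meier / log-rank reporting closes the loop.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
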
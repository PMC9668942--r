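Package: nephroclust
Title: Clustering Clinical Courses of Nephrotic Syndrome with an LSTM
    Autoencoder and Gaussian Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised subtyping of longitudinal nephrotic
    syndrome courses. Five clinical items (serum creatinine, serum albumin,
    dipstick hematuria and proteinuria grades, and the urine
    protein-to-creatinine ratio) observed at five post-biopsy visits are
    embedded into a two-dimensional feature space by an LSTM
    encoder-decoder trained to reconstruct the standardized trajectories;
    the embedding is clustered with a full-covariance Gaussian mixture and
    each case is assigned to the component with the highest weighted
    log-likelihood. Includes a calibrated synthetic-cohort generator with
    planted trajectory archetypes, complete-case preprocessing, BIC-based
    component-count selection, cluster characterization tables and
    likelihood contour grids, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
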
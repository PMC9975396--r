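Package: normfc
Title: Normative Modeling of Functional Brain Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Normative modeling of inter-network functional connectivity in
    resting-state fMRI. Trains an autoencoder (91-46-13-46-91) on healthy
    controls' 91-feature functional-connectivity vectors (Pearson
    correlations between 14 canonical functional brain networks), scores
    deviation of patient groups via per-subject and per-feature
    reconstruction error, and localizes abnormal network-pair connectivity
    through merged-vector thresholding, graph-degree summaries,
    healthy-baseline subtraction, and top-decile pair selection. Includes a
    synthetic-cohort generator (multivariate Gaussian time series drawn
    from structured correlation templates with known injected edge
    perturbations) so the full pipeline is testable end to end with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
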
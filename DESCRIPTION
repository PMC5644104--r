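Package: mdhybrid
Title: Hybrid Neighbor- and Graph-Based Prediction of Microbe-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microbe-disease associations from a sparse binary
    association matrix with a hybrid recommender that averages a
    neighbor-based collaborative-filtering score and a similarity-weighted
    two-step graph-diffusion score. Disease and microbe similarities are
    Gaussian interaction-profile kernels, optionally integrated with a
    precomputed symptom-based disease similarity. Includes ranking-based
    leave-one-out and repeated k-fold cross-validation with candidate-set
    ROC/AUC, three comparison baselines (truncated SVD reconstruction, a
    latent factor model fitted by gradient descent, and a truncated Katz
    index on the heterogeneous network), a cluster-correlation analysis of
    association neighborhoods, and a synthetic data generator with planted
    block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
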
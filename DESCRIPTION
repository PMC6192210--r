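Package: eplmi
Title: Expression-Profile-Based Prediction of lncRNA-miRNA Interactions
Version: 1.0.0
Authors@R: person("EPLMI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Graph-based scoring of all lncRNA-miRNA pairs of a bipartite
    interaction network by two-way resource diffusion (EPLMI), driven by
    expression-profile, functional (annotation-overlap) or sequence
    similarity of the two node classes.  Includes five classical baselines
    (memory-based collaborative filtering on either side, truncated SVD,
    a latent factor model, and the Katz index on the heterogeneous graph),
    leave-one-out and repeated k-fold cross-validation with rank-based
    ROC/AUC, an expression-coherence analysis of identified versus
    unidentified interaction partners, and a synthetic generator of
    planted-block bipartite networks with block-correlated expression
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
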
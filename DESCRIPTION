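Package: sshapelet
Title: Sequence Shapelets for Sparse Multi-Variate Time-Series Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase transformation framework that converts sparse,
    variable-length, irregularly sampled multi-variate time-series features
    into single-valued features usable by any classifier. Each non-empty
    record is z-normalized, optionally compressed by piecewise aggregate
    approximation (PAA), and discretized into a symbol string by symbolic
    aggregate approximation (SAX); a class-distinctive subsequence (an
    "s-shapelet") is then selected per feature by maximizing the information
    gain of an optimal distance-threshold split; finally every record is
    encoded as the sliding-window edit distance to its feature's s-shapelet.
    Three strategies (plain, mc, lr) exploit records that are missing not at
    random, turning feature sparsity itself into signal. Includes a synthetic
    data generator with planted motifs and class-conditional missingness, and
    an evaluation harness (stratified cross-validation, random forests, AUC,
    sparsity-threshold sweeps, Wilcoxon paired comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    ranger,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'sshapelet-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'data-model.R'
    'discretization.R'
    'shapelet-discovery.R'
    'transformation.R'
    'synthetic-data.R'
    'evaluation.R'
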
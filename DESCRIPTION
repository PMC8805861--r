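Package: dirconn
Title: Directed Functional Connectivity from Lagged Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-brain directed functional connectivity networks from
    regional activation time series using the antisymmetric part of the lagged
    correlation matrix, alongside symmetric, zero-lag and bivariate Granger
    causality networks. Thresholds networks across a density range, computes
    directed graph-theory measures (in/out degree, global and local efficiency,
    cycle clustering, transitivity, Louvain modularity, diameter) in binary and
    weight-retaining modes, integrates nodal measures over densities (AUC), and
    tests group differences with covariate-adjusted permutation tests and
    Benjamini-Hochberg FDR correction. Includes a vector-autoregressive
    simulator with known directed ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    graphics,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
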
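Package: dfcmapper
Title: Topological Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis of
    multi-subject region-by-time activity matrices, followed by a topological
    characterization of the resulting state space: Manhattan state distances,
    Vietoris-Rips persistent homology (dimensions 0 and 1), a Mapper shape
    graph with persistence-guided parameter tuning, random-walk community
    detection with a connector/cyclic/bridge node taxonomy, within- and
    between-network connectivity-weight time series correlated with a
    continuous stimulus rating, penalized piecewise-linear change-point
    detection, and phase-randomized surrogate significance testing. Includes
    a synthetic-data generator with planted covariance regimes so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
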
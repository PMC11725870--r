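Package: hots
Title: Reversible Aggregation Analysis of Membrane Protein Cluster Size
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative framework for higher-order transient structures
    (HOTS), the reversible self-clusters of membrane proteins that show
    monotonically decreasing size distributions. Provides the closed-form
    two-dimensional reversible-aggregation model (n-mer densities, critical
    concentrations, phase-transition series), mass-constrained fitting of
    measured cluster size distributions with a shared global cohesion
    energy, a competing attractor (scaffold/raft) model for model
    discrimination, a lattice Monte Carlo simulator of sticky
    excluded-volume random walkers, point-pattern statistics for labeled
    protein coordinates on membrane sheets (single-linkage clustering,
    nearest-neighbor/CSR tests, pairwise-distance peaks, binomial label
    thinning), and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
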
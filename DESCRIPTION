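Package: kurnet
Title: Kuramoto Whole-Brain Network Models with Frequency Optimization and
    Simulated Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mirrored directed and undirected structural connectomes,
    simulates functional connectivity (FC) with Kuramoto phase oscillators in
    the BOLD frequency band, tunes per-node natural frequencies against target
    FC networks using minimum-control-energy node scores on a stabilized
    linear network model, and applies graded unilateral connectivity lesions
    to quantify hypo- and hyperconnectivity and weighted global-efficiency
    loss. Includes a synthetic-data generator (connectomes, target FC, and
    BOLD-like series) so the full pipeline runs and is tested at desk scale,
    and a config-driven stage runner for end-to-end analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
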
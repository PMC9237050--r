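Package: neurocrit
Title: Personalized Whole-Brain Criticality Analysis on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates stochastic three-state (inactive/active/refractory)
    excitable dynamics with homeostatic plasticity on individual structural
    connectomes, quantifies criticality through the threshold profile of the
    largest and second-largest active cluster, synthesizes BOLD-like signals
    and functional connectivity from the simulated activity, computes
    structural graph metrics (average degree, modularity, global efficiency,
    connectivity disorder), and maps criticality indexes onto structural
    edges with a cross-validated ridge regression model. Ships a synthetic
    connectome cohort generator (healthy, lesioned, remodeled) so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
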
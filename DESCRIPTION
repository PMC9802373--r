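Package: plectofluct
Title: Extension Fluctuations and Topological Domains of Supercoiled DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure the size and dynamics of topological domains in
    supercoiled DNA from magnetic-tweezers extension fluctuations. Implements
    the Moroz-Nelson prebuckling model and the two-phase (stretched versus
    plectonemic) coexistence model for the mean and variance of the tether
    extension, a Metropolis Monte Carlo simulator of a discretized
    self-avoiding twistable wormlike chain at fixed linking number with
    optional protein-bridging constraints, generators for synthetic
    bead-tracking traces with Ornstein-Uhlenbeck correlation and Markov state
    switching, and the analysis pipeline that converts variance changes into
    looped-domain sizes, plectoneme torsional stiffness, and loop kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
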
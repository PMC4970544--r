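Package: vwforce
Title: Force Spectroscopy Kinetics and Brownian Dynamics of Shear-Loaded
    von Willebrand Factor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-molecule force spectroscopy (SMFS) of the
    blood protein von Willebrand factor and for coarse-grained Brownian
    dynamics of a wall-grafted VWF multimer under shear flow. Detects
    rupture events in force-distance cycles, computes binding
    probabilities and per-velocity force statistics, fits the
    single-barrier Bell-Evans (Evans-Ritchie) model and the
    Bullerjahn-Sturm-Kroy (BSK) model to rupture forces by maximum
    likelihood across AFM and MD loading-rate regimes, and propagates a
    bead-spring chain with wall-corrected hydrodynamic interactions to
    obtain tensile-force profiles and force-dependent complex lifetimes.
    Includes a seeded synthetic-data generator for traces and rupture
    datasets so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
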
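Package: quadfold
Title: Bias-Exchange Metadynamics and Ensemble Analysis for G-Quadruplex Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for studying G-quadruplex folding pathways with
    bias-exchange metadynamics (BEMD) on analytic toy landscapes and with
    statistical analysis of conformational ensembles. Provides the four
    collective variables used to drive and project quadruplex folding
    simulations (fraction of native contacts, distance RMSD of the backbone,
    cation-O6 coordination number, radius of gyration), a metadynamics engine
    with Gaussian-bias bookkeeping, free-energy readout and a Metropolis-like
    replica-exchange criterion, histogram free-energy-landscape estimation
    with basin identification and convergence diagnostics, leader clustering
    of trajectory frames, per-intermediate structural statistics
    (hydrogen-bond probability maps, ion-binding profiles, syn/anti
    glycosidic-torsion classification, unfolding-pathway graphs), and
    synthetic-data generators that produce toy quadruplex structures and
    ensembles with planted statistical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
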
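Package: pmfgate
Title: Adaptive Umbrella Sampling, WHAM Free-Energy Maps and pH-Gating
    Models for Potassium Channel Permeation
Version: 0.1.0
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Desk-scale toolkit for studying ion permeation and gating in
    potassium channels. Provides analytic free-energy landscapes with a
    biased Brownian-dynamics sampler as a stand-in for molecular dynamics,
    self-learning adaptive placement of 2D umbrella-sampling windows along
    low free-energy valleys, unbiasing by the weighted histogram analysis
    method (WHAM), combination of independent runs, interval-based
    statistical error maps, location of ion-occupancy states and minimax
    (widest-path) barriers on potential-of-mean-force maps, occupancy and
    permeation-event counting from pore-axis coordinate series, and
    Hill and two-sensor Monod-Wyman-Changeux models of proton-dependent
    open probability with a constrained fitting workflow.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
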
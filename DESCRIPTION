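Package: veinsemble
Title: Deep Ensemble Learning for Single-Sample Finger-Vein Identification
Version: 0.1.0
Authors@R: person("Vein", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for finger-vein identification when only a single
    enrollment image per finger is available. From one near-infrared image
    the package derives six feature maps (original, segmented vein map,
    local binary patterns and Gabor textures of each), trains one small
    convolutional network per map, measures inter-map similarity with the
    phase-congruency/gradient feature similarity index (FSIM), and combines
    the weak classifiers into a score- and loss-gated weighted voting
    ensemble. Training schedules support FSIM-driven shared learning across
    feature maps and loss-driven learning-speed adjustment. A seeded
    synthetic vein-image generator with ground-truth vessel masks emulates
    the two-session single-sample-per-person acquisition protocol so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
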
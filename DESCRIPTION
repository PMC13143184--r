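Package: castate
Title: Classification of Stochastic Intracellular Calcium Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates cytosolic calcium (Ca2+) concentration dynamics in the
    Houart three-variable model of inositol trisphosphate gated Ca2+-induced
    Ca2+ release, both deterministically and under intrinsic molecular noise
    via the chemical Langevin equation integrated with the Euler-Maruyama
    scheme. Trajectories are labeled automatically into eight dynamical
    regimes (steady state, oscillatory, bursting, period-2/3/4, chaotic,
    quasiperiodic) from their deterministic dynamics, assembled into balanced
    labeled datasets spanning system-size (noise) levels, and classified with
    a large-kernel one-dimensional convolutional network trained by Adam with
    early stopping. FFT-feature support vector machine and random forest
    baselines, impulsive-noise robustness experiments, confusion-matrix
    metrics, and Fura-2 ratio experimental trace ingestion are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
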
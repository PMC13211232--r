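Package: bedfall
Title: Physics-Based Simulation and Prediction of Fall-from-Bed Risk from Static Posture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fall-from-bed episodes with a lightweight rigid-link
    physics engine (a humanoid dropped onto a box bed above a floor plane),
    samples diverse initial in-bed postures (pose-stratified or fully random),
    detects falls by non-hand floor contact within a fixed rollout window, and
    assigns discounted time-to-fall risk labels on a 30 frames-per-second grid.
    Each episode is summarised as a 13-keypoint 2D skeleton normalised to the
    bed footprint, and regression models (multilayer perceptron, 1D
    convolutional network, graph convolutional network, random forest, LSTM)
    are trained to predict the continuous risk score from that single static
    posture. Includes evaluation with threshold-free and calibrated-threshold
    metrics, per-posture subgroup reports, a physics-free surrogate data
    generator for fast testing, and experiment drivers for sampling-strategy
    ablations and training-set-size scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
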
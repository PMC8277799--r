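Package: rotakin
Title: Movement Sub-Structure Analysis of Rotarod Paw-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the movement sub-structure of rodent rotarod
    trials from video-tracked paw coordinates. Reads and calibrates exported
    paw trajectories, derives per-axis speed and acceleration, and computes
    intra-session kinematic features including approximate entropy and
    spectral arc length movement smoothness. Implements the cumulative
    early-segment predictor scan (Spearman correlation of first-T-second
    features against time-to-fall), two-group and paired comparisons,
    PCA with MANOVA-Wilks group separation, and an early-versus-late
    support vector machine classifier over per-second feature bins with
    kernel selection by ten-fold cross-validation. A synthetic trajectory
    simulator generates accelerating-rod schedules and quasi-periodic
    stepping trajectories with controllable regularity, smoothness, slips
    and fall times so that every analysis stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
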
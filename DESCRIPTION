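Package: gaitdecode
Title: Gait-Phase Recognition and Ahead-of-Time Joint-Angle Prediction
    from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A muscle-activation-driven motion decoder for lower-limb
    surface electromyography (sEMG). Provides a synthetic gait simulator
    (quasi-periodic four-phase gait, phase-locked activation bursts,
    electromechanical lead of the EMG envelope over the joint angle,
    foot-switch traces), an activation-dynamics model (recursive neural
    activation filter and nonlinear activation map), per-phase muscle
    effect analysis for sensor reduction, sliding-window time-domain EMG
    features, LSTM-based gait-phase classification and phase-and-EMG
    coupled 40-ms-ahead joint-angle prediction, and a fine-tuning scheme
    that adapts trained decoders to the signal-distribution shift induced
    by exoskeleton assistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
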
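Package: mibci
Title: Simulation and Evaluation of Gamified Motor-Imagery BCI Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and evaluate a gamified motor-imagery
    brain-computer interface (BCI) rehabilitation protocol. Generates
    synthetic 16-channel EEG with lateralized event-related
    desynchronization of the mu and beta rhythms, runs the standard
    offline decoding chain (band-pass and notch filtering, epoching,
    artifact rejection, Common Spatial Patterns, log-variance features,
    linear discriminant analysis, 10-fold cross-validated timepoint
    accuracy curves), drives the cheese-versus-rat serious-game state
    machine from classifier events, orchestrates the two-session
    calibration/training study protocol, and provides the accompanying
    statistical stage (repeated-measures ANOVA with sphericity
    corrections, group comparisons) and Likert questionnaire scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
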
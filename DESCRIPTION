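Package: mmgtorque
Title: Elbow Flexion Torque Estimation from Mechanomyography with
    Equilibrium-Optimizer Feature Selection and Random-Forest Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating elbow flexion torque from mechanomyography
    (MMG) recorded during neuromuscular electrical stimulation. Implements the
    full pipeline: zero-phase Butterworth filtering and transient trimming of
    synchronized MMG/torque recordings; sliding-window extraction of twelve
    time- and frequency-domain MMG features (RMS, band energies, spectral
    moments, spectral flux and flatness, zero-crossing rate, Hjorth mobility);
    Z-score outlier censoring, min-max scaling and grey relational screening;
    a histogram-binned stratified train/test split for continuous targets; a
    random-forest regression model exposing four tunable hyperparameters; and
    the Equilibrium Optimizer (EO) and General Learning Equilibrium Optimizer
    (GLEO) metaheuristics for wrapper feature selection, hyperparameter
    tuning, or both jointly, with a grid-search baseline. A seeded synthetic
    signal generator emulating stimulation-evoked MMG/torque coupling is
    included for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
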
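Package: egmseg
Title: Delineation of Intracavitary Electrograms and Quantification of
    Decrement-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automatic delineation of bipolar intracavitary
    electrograms (EGM) recorded in the coronary sinus and for the downstream
    quantification of decrement-evoked potentials. Provides a rule-based
    synthetic trace generator with conditional log-normal amplitude models,
    1D U-Net and W-Net encoder-decoder segmentation networks with optional
    efficient channel attention (implemented natively on BLAS matrix
    operations), Dice and edge-sensitivity losses with a reproducible
    training loop, per-lead mask-to-interval delineation with majority
    voting across the catheter leads, stimulus-response matching with
    clinical exclusion rules and cross-correlation-corrected decrement
    classification, and the full set of detection and delineation metrics
    (precision, recall, Dice, onset and offset errors, false-positive
    filtering and merged-class variants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
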
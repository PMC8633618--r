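Package: remhep
Title: Heartbeat-Evoked Potentials Across REM Sleep Microstates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for contrasting heartbeat-evoked
    potentials (HEPs) between phasic and tonic rapid-eye-movement (REM)
    sleep microstates and resting wakefulness. Provides a synthetic
    polysomnography generator with known ground truth, EDF input/output,
    EOG-based phasic/tonic segment classification, ECG R-peak detection
    and time-domain heart-rate variability, R-peak-locked epoching and
    averaging, spatio-temporal cluster-based permutation statistics with
    a compiled Monte-Carlo core, ECG-artifact confound controls
    (windowed amplitude contrasts, repeated-measures ANCOVA, contrast
    correlations, pointwise permutation tests with FDR correction), and
    a surrogate-heartbeat specificity test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
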
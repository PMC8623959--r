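Package: lrfa
Title: Laser Resonance Frequency Analysis for Implant Stability Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning-based laser resonance frequency
    analysis (L-RFA) of orthopedic pedicle screws. Converts laser-Doppler
    vibrometer time series into averaged impulse responses and amplitude
    spectra, extracts band-wise spectral features (peak, centroid, average
    intensity, dispersion, kurtosis, skewness), ranks features by
    bootstrap-Lasso selection frequency, and predicts peak insertion torque
    with an RBF-kernel support vector regression tuned by power-of-two grid
    search under torque-stratified cross-validation. Includes a synthetic
    damped-oscillation vibration simulator emulating monoaxial and polyaxial
    (movable-head) screw behaviour so the whole pipeline can be exercised
    and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
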
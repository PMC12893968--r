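Package: ulmpipe
Title: Super-Resolution Ultrasound Localization Microscopy Pipeline and
    Diagnostic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of high-frame-rate contrast-enhanced
    ultrasound for super-resolution microvascular imaging. Provides a
    synthetic phantom generator (vessel trees, flowing microbubbles,
    bolus time-intensity curves, two-group lesion cohorts), SVD
    spatiotemporal clutter filtering, microbubble detection and
    sub-pixel localization, inter-frame tracking with normalized
    cross-correlation gating, quantitative microvascular metrics
    (velocity, tortuosity, diameter, fractal dimension, microvascular
    density, distribution and flow-direction classification),
    time-intensity-curve parameters, and the diagnostic statistics
    layer (chi-square, Fisher, t, Mann-Whitney, Cohen's kappa, logistic
    regression, ROC with DeLong intervals, multimodality combinations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
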
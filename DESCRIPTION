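Package: spafnirs
Title: Systemic-Physiology-Augmented fNIRS Model Comparison and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-subject analysis pipeline for systemic-physiology-augmented
    functional near-infrared spectroscopy (SPA-fNIRS). Provides a synthetic
    multi-session data generator with known ground truth, preprocessing from raw
    dual-wavelength intensities to hemoglobin concentrations (optical density,
    scalp coupling index pruning, temporal derivative distribution repair,
    modified Beer-Lambert law, filtering and resampling), block averaging with
    confidence intervals, physiology regressor conditioning with cross-correlation
    lag optimization and temporally embedded canonical correlation analysis,
    six general-linear-model nuisance-correction models, nuisance regression
    denoising, and ICC(3,k) test-retest reliability with per-region session
    variances and model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
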
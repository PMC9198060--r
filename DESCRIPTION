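Package: bloodgas
Title: Noninvasive Blood Gas Estimation with Selective Abstention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous noninvasive estimation of blood pH and arterial CO2
    tension (PaCO2) for mechanically ventilated patients, from bedside
    monitor and ventilator measurements plus the most recent invasive blood
    gas. Implements a key-predictor pairwise regression in which sigmoid
    basis functions of the previous pH modulate ridge-fitted linear effects
    of the noninvasive predictors, a fold-ensemble measure of prediction
    uncertainty with calibrated abstention, per-sample predictor importance
    ranking, physiologic baseline models (alveolar dead-space fraction with
    Henderson-Hasselbalch, and a capnography-free linear regression), an
    evaluation suite (error percentiles, CLIA agreement, Bland-Altman,
    risk-coverage and time-lag analyses), and a synthetic ventilated-cohort
    simulator for end-to-end testing without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
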
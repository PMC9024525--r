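Package: respnet
Title: Respiratory-Phase Classification and Lung Tumor Displacement
    Prediction from Chest-Wall Surrogate Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for respiratory motion management in lung radiotherapy
    built around an external chest-wall surrogate signal. Provides a
    pseudopatient breathing simulator (Lujan-type cos-power waveforms with
    configurable irregularity), breathing-cycle detection and ten-phase
    respiratory binning, assembly of time-lagged feature windows, a
    hand-written time-series feed-forward network in which three lagged
    input vectors are injected through shared weights into hidden layers
    1, 3 and 5 (Softmax classifier head for the respiratory phase, ReLU
    regression head for longitudinal tumor displacement in mm), and the
    matching evaluation metrics: per-phase precision/recall/F1 with macro
    total accuracy, and MSE/MAE/R-squared for regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
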
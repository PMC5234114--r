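Package: osasev
Title: Obstructive Sleep Apnea Severity Classification from Nocturnal Breathing Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies obstructive sleep apnea (OSA) severity from single-channel
    nocturnal breathing-sound recordings. Implements stationary-noise reduction by
    spectral subtraction, quantized energy-level transition-probability features in
    the time domain, cyclostationarity-based spectral features built from a running
    mean cyclic spectral density compressed by non-negative matrix factorization,
    wrapper feature selection with linear forward search, and a linear support
    vector machine severity model evaluated by leave-one-out cross-validation.
    Includes a synthetic sleep-audio cohort generator so every stage can be
    exercised without patient recordings.
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
    graphics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
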
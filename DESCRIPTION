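Package: vtdetect
Title: Automated Ventilatory Threshold and Respiratory Compensation Point
    Detection from Cardiopulmonary Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated determination of the first ventilatory threshold (VT1)
    and the respiratory compensation point (VT2) from breath-averaged
    gas-exchange data collected during incremental cycle-ergometer tests.
    Detection combines excess-CO2, excess-ventilation and V-slope signals with
    a single-changepoint search that minimises a Gaussian variance cost over a
    trimmed window of the test. The package also provides quality-control
    rules for combining independent evaluator annotations, method-agreement
    statistics (Bland-Altman limits of agreement, paired TOST equivalence,
    two-way random-effects ICC, t tests), and a synthetic test generator with
    planted thresholds so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
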
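Package: coolact
Title: Accumulated Cooling Temperature and Inflorescence-Formation
    Modelling for Phalaenopsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Thermal-time tools for cool-induced spiking (inflorescence
    formation) in Phalaenopsis orchids.  Computes the accumulated cooling
    temperature (ACT) index in degree-hours from day/night set-point
    regimes or hourly temperature logs, fits the three-parameter sigmoid
    inflorescence-formation model by nonlinear least squares with the
    usual nonlinear-regression fit statistics (R-squared and residual
    standard error), inverts the fitted curve to schedule the number of
    cooling days needed to reach a target spiking percentage, and
    simulates per-plant induction in cohorts so that fitting and
    index-comparison procedures can be exercised end to end without
    access to raw greenhouse records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
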
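Package: glyvar
Title: Glycaemic Variability Metrics and Single-Draw Predictive Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the standard continuous-glucose-monitoring (CGM)
    glycaemic-variability statistics (SD, %CV, range, IQR, J-index, MAGE,
    M-value, IGC, MODD, CONGA) from 5-minute interstitial glucose traces,
    together with two laboratory indices obtainable from a single blood
    draw - the glycated albumin to HbA1c ratio and the fasting C-peptide
    to fasting plasma glucose index - and the statistical pipeline linking
    them: normality testing, univariate screening, stepwise multivariate
    regression, serial-cutoff ROC optimisation with Youden operating
    points, combined-criterion risk classification, and glucose-band time
    distributions. Includes a calibrated synthetic cohort generator for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
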
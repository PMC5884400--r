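Package: apcie
Title: Age-Period-Cohort Decomposition of Cancer Mortality with the Intrinsic Estimator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for decomposing cancer mortality trends into age, period and
    birth-cohort effects with Poisson log-linear rate models identified by the
    Intrinsic Estimator (the minimum-norm solution orthogonal to the design's
    null vector). Includes a reader for WHO Mortality Database flat files,
    construction of age-by-period rate tables on the Lexis diagram with
    missing-year imputation, direct age standardization against the Segi (1960)
    world standard population, a synthetic-data generator with known ground
    truth for validation, and a config-driven pipeline that reproduces a full
    multi-country, multi-cancer mortality analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
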
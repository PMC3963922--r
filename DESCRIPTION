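Package: gulldemog
Title: Demography of Colonial Waterbirds from Capture-Resight and Census Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the demographic analysis of colonial waterbird
    populations monitored by individual marking and nest censuses.
    Implements constrained Cormack-Jolly-Seber survival/resighting models on
    m-array sufficient statistics with an age/time/colony/covariate model
    grammar, AICc model selection, analysis-of-deviance (ANODEV) covariate
    tests, U-CARE-style contingency-table goodness-of-fit, count-based
    stochastic population growth (Dennis regression), stage-structured matrix
    projection with an immigration correction, and a synthetic-data generator
    emulating age-structured capture-resight and census monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
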
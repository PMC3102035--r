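Package: fixedcohort
Title: Fixed Cohort Bias in Retrospective Birth Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to demonstrate, quantify and remove the fixed cohort bias
    that arises in retrospective birth cohorts defined by a fixed birth-date
    window: short gestations conceived before the window starts and long
    gestations conceived near its end are systematically missed, creating
    artificial seasonal patterns in gestation length. The package provides a
    Monte-Carlo simulator of null and seasonal-effect birth cohorts with
    synthetic daily weather, the conception-date trimming rule that removes
    the bias, and proportional-hazards estimation of month-of-conception and
    time-dependent rolling-mean temperature effects on gestation length via
    counting-process expansion and a centered spline basis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    splines,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
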
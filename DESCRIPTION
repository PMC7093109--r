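Package: smokemort
Title: Smoking-Attributable Mortality via Lung-Cancer-Indexed Indirect Estimation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the mortality burden of cigarette smoking in
    high-income countries. Implements the lung-cancer-indexed indirect method
    (Smoking Impact Ratio) for attributing stratified death counts to smoking,
    closed-form attributable-fraction and cessation-benefit algebra, decade-grid
    geometric interpolation, backcasting and cumulation of attributable-death
    series, lagged cigarettes-per-death ratios, and a seeded synthetic
    vital-statistics generator with retained ground truth for parameter-recovery
    and oracle testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
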
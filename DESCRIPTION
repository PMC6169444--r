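Package: nitrorisk
Title: Nitrate and Nitrite Drinking-Water Risk Assessment with Monte Carlo
    Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for screening groundwater nitrate and nitrite
    concentrations against drinking-water standards and estimating the
    non-carcinogenic health risk of chronic ingestion. Handles left-censored
    (non-detect) well measurements under explicit substitution policies,
    computes seasonal averages and descriptive statistics, runs the standard
    exceedance and hypothesis tests used in water-quality surveys, evaluates
    the EPA target hazard quotient (THQ) and its sum over analytes (TTHQ),
    and propagates input uncertainty through the intake equation by seeded
    Monte Carlo simulation, reporting percentile summaries such as the
    95th-percentile "reasonable worst case". A synthetic well-field
    generator with realistic right-skewed concentrations and censoring
    supports fully reproducible testing, and a pipeline driver writes
    machine-readable report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
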
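Package: stopgo
Title: Three-Outcome Progression Criteria and Sample Size for External
    Pilot Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of stop/pause/go ('traffic light')
    progression criteria for external pilot trials, treated as
    three-outcome hypothesis tests with exact frequentist operating
    characteristics. Computes the classic Sargent and Storer phase II
    operating characteristics and their reformulation in which a pause
    outcome is resolved by a later decision that is wrong with
    probability eta, optionally after an adjustment to the intervention
    whose effect is known up to an interval. Provides constrained
    minimum-sample-size searches for binary (exact binomial) and
    continuous (known-variance normal) endpoints, sensitivity sweeps
    over the design parameters, Monte Carlo validation of the analytic
    operating characteristics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
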
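Package: seqphase2
Title: Bayesian Sequential Monitoring Designs for Single-Arm Phase II Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for single-arm phase II oncology
    trials that jointly monitor binary efficacy (long observation window) and
    unacceptable toxicity (short window) under continuous accrual. Implements
    posterior-probability toxicity monitoring, BOP2-style futility boundaries,
    the time-to-event TOP extension that weights pending patients by their
    fraction of elapsed follow-up, Simon's two-stage design with fixed stage
    sizes, joint efficacy/toxicity TOP monitoring with an optional informative
    toxicity prior borrowed from a concomitant biomarker-defined subgroup, and
    a Monte Carlo engine that evaluates operating characteristics (type I
    error, power, expected sample size, trial duration, early stopping) under
    correlated bivariate binary outcome scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
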
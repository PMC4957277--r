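Package: bayesfactorial
Title: Bayesian Interim Monitoring of 2x2 Factorial Trials with a Binary Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a Bayesian log-link Bernoulli (log-binomial) regression to
    2x2 factorial trial data with a binary outcome, constructs neutral and
    enthusiastic normal priors from historical control rates and elicited
    credible intervals, derives posterior relative risks and risk differences
    for marginal and per-arm comparisons, evaluates quantitative futility,
    safety and efficacy stopping rules, and estimates frequentist operating
    characteristics of a monitoring plan by simulation. Ships the interim
    predischarge-mortality counts of the Optimizing Cooling Trial
    (NCT01192776) as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
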
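Package: trialflow
Title: Decision-Analytic Simulation of Staged Clinical Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the expected flow of effective and ineffective candidate
    treatments through phase II and phase III clinical testing under
    configurable Type-I error and power thresholds, classifies outcomes into
    true/false positives and negatives, attaches a sample-size-driven economic
    layer (program costs, expected returns, profit), searches the phase II
    (alpha, power) space for profit-maximising designs, and propagates
    parameter uncertainty by Monte Carlo probabilistic sensitivity analysis
    with binomial portfolio simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
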
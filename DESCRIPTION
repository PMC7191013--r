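Package: sbsbn
Title: Safety Behavior Sampling and Bayesian Network Analysis of
    High-Risk Unsafe Work Behaviors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing safety-behavior-sampling (work sampling)
    observation campaigns, fitting discrete Bayesian networks over
    workplace behavioral variables by Expectation-Maximization (with
    missing observations handled by exact inference), and ranking the
    drivers of high-risk unsafe behavior through belief-updating
    sensitivity analysis and mutual information.  Includes exact
    posterior inference by variable elimination, a calibrated synthetic
    observation generator for method evaluation, JSON and XMLBIF network
    serialization, and an end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
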
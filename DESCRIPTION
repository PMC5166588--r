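Package: lccusum
Title: Learning-Curve CUSUM Monitoring of Binary Surgical Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential proficiency analysis for consecutive surgical case
    series with a binary adverse outcome. Derives Bernoulli sequential-scheme
    constants (step s, decision limit h) from acceptable and unacceptable
    failure rates and the two error probabilities, runs the learning-phase
    LC-CUSUM chained into a monitoring-phase CUSUM with holding barriers,
    pools prior-study failure proportions into the benchmark rates that
    parameterize both phases, summarizes case-series outcomes (overall,
    windowed and running rates, POP-Q anterior staging and anatomic cure,
    paired pre/post comparison), fits the multivariable logistic model of
    healing-abnormality risk with Wald intervals and Cox & Snell R-squared,
    and generates seeded synthetic cohorts with a learning-curve failure
    mechanism for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
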
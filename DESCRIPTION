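Package: evtvalue
Title: Health and Cost Effects of Faster Endovascular Stroke Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage Markov cohort model quantifying the 5-year health
    (quality-adjusted life years, disability-free days) and healthcare-cost
    effects of faster endovascular treatment (EVT) for large-vessel-occlusion
    ischemic stroke. The short-term stage estimates the 90-day modified Rankin
    Scale (mRS) distribution per hour of onset-to-groin-puncture delay from
    patient-level registry records; the long-term stage simulates annual
    cycles of stroke recurrence and all-cause mortality over five years.
    Outcomes are summarized as Net Monetary Value and Net Monetary Benefit at
    a fixed willingness to pay, with one-way and probabilistic (second-order
    Monte Carlo) sensitivity analyses, population-level extrapolation, and
    banded external-validation comparisons. A synthetic-data module generates
    registry records, follow-up economics, life tables and full parameter
    sets with the statistical structure the analysis assumes, so the entire
    pipeline is testable without access to the original trial data.
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
    MASS
Config/testthat/edition: 3
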
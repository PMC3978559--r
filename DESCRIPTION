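Package: lifecea
Title: Trial-Based Cost-Effectiveness and Cost-Utility Analysis for
    Multi-Arm Lifestyle Intervention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for trial-based economic evaluation of
    three-arm randomized controlled trials of lifestyle interventions.
    Computes EQ-5D-3L utilities under the Dutch tariff (with pluggable
    value sets), area-under-the-curve quality-adjusted life years,
    lifestyle factor scores from public-health guideline adherence,
    societal-perspective costs (health care, productivity via the human
    capital method, respondent time and travel, intervention hosting)
    with consumer-price-index indexing and differential discounting, a
    single-imputation cascade (neighbour mean, last observation carried
    forward, next observation carried backward) with plausibility
    truncation, nonparametric bootstrap incremental analysis with
    dominance classification, net-monetary-benefit acceptability curves,
    and a declarative sensitivity-scenario driver. A seeded synthetic
    trial generator reproduces the statistical structure the analysis
    assumes so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
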
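Package: rrmcea
Title: Cost-Effectiveness Thresholds for Risk-Reducing Mastectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing risk-reducing
    mastectomy (RRM) with risk-stratified breast-cancer screening plus medical
    prevention for women at elevated lifetime breast-cancer risk. Computes
    lifetime cumulative risk under competing mortality, hazard-ratio scaled
    age-specific incidence, discounted costs and quality-adjusted life-years,
    incremental cost-effectiveness ratios, willingness-to-pay threshold
    searches over a lifetime-risk grid, one-way (tornado) and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves, and
    population-level prevented-case arithmetic. Ships a synthetic
    parameter-bundle generator so every stage of the pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
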
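Package: hwle
Title: Healthy Working Life Expectancy from Interval-Censored Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates healthy working life expectancy (HWLE) and related
    health expectancies from biennial longitudinal survey data using an
    age-adjusted five-state (four living states plus death) interpolated
    Markov chain model. Observed multi-year intervals are decomposed into
    12-month interpolation steps whose transition probabilities follow
    multinomial logits; parameters are fitted by weighted maximum likelihood
    on the interval-censored panel, and prevalence-weighted state
    expectancies (HWLE, three further health expectancies, and life
    expectancy as their sum) are computed with simulation-based confidence
    intervals. Includes a synthetic-cohort generator emulating a Health and
    Retirement Study style design (biennial waves, refreshment entry ages,
    survey weights, unknown-state and skipped-wave missingness), the full
    survey coding and cleaning rules (activity-limitation health coding,
    employment coding, irreversible arthritis, BMI-based obesity, census
    regions, date imputation, nearest-wave imputation, exclusions), and a
    stratified study runner with a calendar-period sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
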
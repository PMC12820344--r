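# hwle — healthy working life expectancy from interval-censored panel data

How many years, from age 50, can people expect to be *healthy and in paid
work*? That quantity — healthy working life expectancy (HWLE) — is the
population summary that health-and-work researchers use to compare groups
(with/without arthritis, by sex, education, region, obesity) and to argue
about extending working lives. Estimating it from biennial panel surveys is
awkward: state transitions are only known to happen somewhere between
interviews, people skip waves, answers go missing, and deaths arrive with
month-resolution dates. This package implements the full estimation
pipeline for analysts working with such panels, together with a
synthetic-cohort generator so every stage is testable without access to
restricted survey data.

## The model

A five-state process: 1 = healthy & working, 2 = healthy & not working,
3 = not healthy & working, 4 = not healthy & not working, plus death
(absorbing). Observed multi-year intervals are decomposed into 12-month
interpolation steps; within a step, transitions out of living state *i*
follow an age-adjusted multinomial logit with the self-transition as
reference:

    p_ij(a) = exp(a_ij + b_ij (a - 50)) / (1 + Σ_k exp(a_ik + b_ik (a - 50)))

The likelihood of an observed interval is the matching entry of the ordered
product of step matrices; unknown-state waves (code −1) contribute survival,
skipped waves (−2) are chained across, and deaths are localised to their
final step. Parameters are fitted by weighted maximum likelihood (BFGS,
analytic gradient, Rcpp kernel). Conditional expectancies by starting state
are integrated trapezoidally to age 110 and averaged with the
survey-weighted state prevalence at age 50:

    HWLE = Σ_i w_i e_i1,   LE = Σ_j Σ_i w_i e_ij   (LE ≡ sum of the four
                                                    health expectancies)

with simulation-based standard errors and percentile intervals.

## Worked example

```r
library(hwle)

# a synthetic cohort with known ground truth: 3,000 adults, 14 biennial
# waves, raw survey answers
cfg    <- true_model_config(n_individuals = 3000, seed = 1)
cohort <- generate_cohort(cfg, emit = "answers")

panel <- prepare_panel(cohort$raw)          # all coding/cleaning rules
fit   <- fit_mle(panel)                     # 16 logits, age-adjusted
prev  <- initial_prevalence(panel, 50, 2)   # state mix at ages 50-52
confidence_intervals(fit, prev, n_draws = 500, seed = 2)
```

```
Population health expectancies (years from anchor age)
  healthy_working              9.09
  healthy_not_working         10.28
  not_healthy_working          1.97
  not_healthy_not_working      9.31
  life expectancy (sum)       30.66
  HWLE share of LE: 30%
  HWLE 95% CI: 8.71-9.44; LE 95% CI: 30.19-31.04 (500 draws)
```

The generating model's true values are HWLE 9.17 and LE 30.66 years, so the
pipeline recovers both well within its interval. `run_stratified_analysis()`
refits per stratum and reports a table of HWLE, LE and %HWLE-of-LE per
group; `working_days_lost(hwle_a, hwle_b)` converts an HWLE gap into days
over a 260-day working year; `sensitivity_prevalence_by_wave()` checks the
calendar stability of the anchor prevalence.

The numbered scripts under `analysis/` run the whole study at desk scale —
simulate, prepare, fit, expectancies, stratified tables, sensitivity — and
write their tables under `results/`.

## Method documentation

The methods vignette (`vignettes/hwle-methods.Rmd`) describes the model and
its assumptions, the likelihood contributions wave by wave, the survey
coding rules, what the synthetic generator does and does not emulate, the
numerical choices (fractional steps, tolerances, covariance handling), and
known limitations.
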
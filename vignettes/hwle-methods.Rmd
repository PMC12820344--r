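---
title: "Estimating healthy working life expectancy from interval-censored panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating healthy working life expectancy from interval-censored panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimand and the model

Healthy working life expectancy (HWLE) from age 50 is the expected number of
years a person spends simultaneously *healthy* (no limiting long-standing
illness) and *in paid work*. The package models a five-state process — the
2×2 grid of healthy/not-healthy by working/not-working (states 1–4) plus
death as an absorbing state — observed at biennial survey interviews, so
that transitions are interval censored: we know the states at interview
dates, never the transition times between them.

The estimator is an interpolated Markov chain: each observed interval is
decomposed into short *interpolation steps* (12 months by default), and
within a step the transition probabilities out of living state $i$ follow a
multinomial logit with the self-transition as reference,

$$
p_{ij}(a) = \frac{\exp(\alpha_{ij} + \beta_{ij}(a - 50) + \gamma_{ij}'x)}
  {1 + \sum_k \exp(\alpha_{ik} + \beta_{ik}(a - 50) + \gamma_{ik}'x)},
$$

where $a$ is age at the start of the step and $x$ optional binary
covariates. By default all 12 ordered pairs among the living states and all
four living→dead transitions are permitted (16 logits); the dead row is a
unit vector. Ages are centred at 50, so intercepts are log-odds of a
one-step transition at the anchor age — this is a pure reparameterisation
that improves optimiser conditioning and makes ground-truth values easy to
read.

The probability of an observed interval is the corresponding entry of the
ordered product of step matrices, ages advancing one step at a time. The
weighted log-likelihood of a person's observation sequence is evaluated with
a scaled forward algorithm over the five states:

* an observed living state collapses the forward vector to that state;
* an unknown-state wave (code −1: the respondent participated but health or
  work answers are missing) zeroes the dead entry and renormalises — it
  contributes the probability of being alive and marginalises over the
  unknown state, including when it is the *origin* of the next interval;
* skipped waves (code −2: no participation, vital status unknown)
  contribute nothing and the interval chains across them;
* a month-resolution death date contributes the probability of surviving in
  any living state to the last step before death and then dying within that
  step;
* a person alive at their last interview is right-censored there, and a
  single observation with no follow-up contributes zero.

When every state is known this reduces exactly to the usual sum of log
interval probabilities over consecutive observation pairs. Waves with
unknown state *before* the first known living state carry no usable
information (there is no initial state distribution in the likelihood) and
are skipped.

Intervals that are not whole multiples of the step end with a fractional
step $P_f = (1-f)I + fP$, linear interpolation between the identity and the
full step matrix. We chose this over scaling the logits by $f$ because it is
the only choice of the two that is continuous in the observation dates: as
$f \to 0$ the factor tends to the identity (a logit scaled to zero tends to
a *uniform-ish* row instead), and the probability of any move — death
included — is proportional to the fraction of the step elapsed.

Maximisation uses BFGS with an analytic gradient obtained by reverse
accumulation through the forward recursions (the compiled kernel also
deduplicates step matrices, which depend only on age at month resolution,
the step fraction, and the covariate combination). Convergence is declared
when the relative log-likelihood change falls below 1e-9 or the gradient
max-norm falls below 1e-5; non-convergence is reported, never silent. The
covariance is the inverse observed information, from forward differencing of
the analytic gradient; eigenvalues that are negative within differencing
noise (more than $-10^{-6}$ times the largest) are clamped to zero, anything
worse is reported as "covariance unavailable" rather than patched.

## From transition model to expectancies

Conditional expectancies $e_{ij}$ — expected years in state $j$ from age 50
in state $i$ — propagate occupancy vectors by repeated step-matrix
multiplication to a horizon of 60 years (age 110), integrating occupancy
with the trapezoidal rule (the standard half-interval life-table
correction; the integration rule is not dictated by the method, and the
Monte-Carlo oracle in the tests counts trajectory occupancy with the same
rule so the two estimate the same quantity). A warning is raised if more
than $10^{-4}$ living occupancy remains at the horizon.

Population expectancies weight the starting states by the survey-weighted
observed prevalence at the anchor age, by default in the window [50, 51);
the analyses here use [50, 52) because refreshment entry ages mean few
respondents are interviewed at exactly 50 — widening the window trades a
little age mismatch for a much less noisy anchor. HWLE is the expectancy of
state 1; life expectancy is the sum of the four expectancies *by
construction*, an identity asserted to 1e-10 in the tests.

Standard errors and 95% intervals come from parametric simulation: draw
parameter vectors from the multivariate normal of the estimates, recompute
all expectancies per draw, take draw SDs and 2.5/97.5 percentiles (1,000
draws by default, deterministic given a seed). When the function receives an
*estimated* prevalence object it also resamples the anchor weights per draw
(Dirichlet with the observed effective counts): at realistic sample sizes
the anchor noise is the same order as the parameter noise, and intervals
that ignored it covered the true population HWLE in clearly fewer than 95%
of synthetic replicates. Passing a bare weight vector keeps the intervals
parameter-only. This simulation approach estimates the same asymptotic
quantity as an analytic delta method, and is testable through its scaling
and coverage behaviour.

Two reporting helpers mirror the published arithmetic: HWLE as an integer
percentage of LE (rounded half away from zero), and working days lost
between two HWLE values over a 260-day working year, optionally rounded to
the nearest hundred days.

## Survey coding rules

The preparation module implements the coding rules of the source survey
design at month resolution (days are never recorded; day 15 anchors age
arithmetic, and age is exact fractional years, days/365.25):

* **Health**: healthy iff no "yes" on the three activity-limitation items
  (paid work, housework, any activities); *missing only when none of the
  three was answered*. A partial response with no "yes" codes healthy — the
  stricter "all three answered" variant would leave partial responses
  uncodable.
* **Work**: working iff the employment item is "working now"; any other
  stated category is not working.
* **State**: dead → dead; both classifications present → the 2×2 grid;
  either missing → −1; no participation → −2.
* **Arthritis** is an ever-diagnosis and irreversible: answers are first
  gap-filled from the nearest wave (ties to the earlier wave, so no future
  information), then made monotone — a "no" after a "yes" is overridden,
  and arthritis is absent at and before an explicit "no" unless an earlier
  "yes" exists. Imputation-then-monotone is the composition used because
  nearest-wave imputation is the generic rule for all time-varying
  covariates while irreversibility is a modelling assumption about the
  final series.
* **Obesity** is BMI ≥ 30 (inclusive), BMI from baseline height and
  per-wave body weight (703 × lb/in² for US units); implausible heights
  (outside 1.2–2.3 m) are treated as missing with a warning.
* **Region** is the census grouping of the 50 states plus DC.
* **Dates**: missing birth month → June; missing death month → June unless
  that precedes a participation date (→ December); a recorded death month
  earlier than a same-year interview is considered erroneous and moved to
  December; death records without dates are ignored.
* **Weights**: each person carries the first non-zero cross-sectional
  weight from a wave at age ≥ 50; persons with none are ineligible.
* **Exclusions**: missing any fixed covariate (sex, education, ethnicity,
  region); a time-varying covariate missing at *all* participated waves;
  no qualifying weight; no observation at age 50+. Every exclusion is
  logged with a reason.

Preparation is idempotent: an already-coded panel passes through unchanged.

## The synthetic cohort

The generator stands in for restricted survey data and defines the study
conditions used by every statistical test: 14 biennial waves (24-month
spacing) from 1994, entry ages uniform over 50–60 at month resolution,
initial living-state distribution (0.55, 0.20, 0.10, 0.15), covariate
prevalences matching a large US survey of older adults (55% female, 77%
high-school education, region mix 17/23/44/16% NE/MW/S/W, ethnicity
19/72/9% Black/White/other, 30% baseline obesity), baseline arthritis 40%
with a 3.5%-per-step irreversible onset hazard, and 5% unknown-state plus
5% skipped-wave missingness (participation rates are not published for the
source design; these are configurable defaults). Survey weights default to
constant 1 — the design weights of the source survey cannot be emulated,
and any positive weights exercise the weighted-likelihood path.

Ground-truth transition logits were chosen once so that the implied
population quantities are plausible for a US population at age 50 — HWLE
9.17 years and LE 30.66 years, with retirement-like exits from work rising
with age, return-to-work rates falling, and Gompertz-like mortality
(log-hazard slope 0.09/year) — and then frozen.

Each individual's complete path is simulated step by step from the same
step-transition model the estimator fits (grid = the 12-month interpolation
step by default; a finer grid, e.g. monthly, uses the fractional-step
matrices and exists to probe discretisation bias). States are observed at
interview dates; missingness is injected afterwards and never touches death
dates, and the last participated wave of a decedent is never converted to a
skipped wave. Death months use the end-of-step convention, so recovery
tests measure estimator error rather than a generator/estimator timing
mismatch (a month-level jitter would add a small, deliberate
misspecification). In answers mode the generator emits raw survey answers —
limitation items, the employment item, arthritis diagnoses with occasional
missing answers, heights and per-wave body weights consistent with the
obesity indicator, and a US state within the person's region — to exercise
the full coding pipeline.

What the generator does *not* emulate: design-based survey weights and
clustering, proxy interviews, questionnaire skip logic, calendar-period
effects (the transition process is stationary in calendar time by
construction — though the observed state mix at a fixed age still drifts
over the first decade while entry cohorts, which all start from the same
initial state distribution, equilibrate; the calendar-period sensitivity
analysis flags exactly that), and item-level response styles. Passing tests therefore demonstrate that the
estimator recovers a process of the assumed form from data with the assumed
observation scheme — not that the assumed form is true of any real survey.

## Stratified analysis and sensitivity

The study runner refits the model per stratum (the default plan: overall;
arthritis; and sex, education, region, ethnicity and obesity each crossed
with arthritis), mirroring a table of stratified estimates; a pooled fit
with covariates in every logit is available through
`transition_structure(covariates = ...)` and `fit_mle()`. For the
time-varying stratifiers (arthritis, obesity) a person's series is split
into maximal runs of constant value: each transition is used exactly once,
classified by its status at the interval's origin, and a death date stays
with the final run. Strata below a minimum size, or whose fit fails, are
skipped with a logged diagnostic. Time-varying covariates in pooled fits
are held at their value at each interval's origin observation.

The calendar-period sensitivity computes the survey-weighted prevalence of
the four living states at target ages (55, 60, 65, ±1 year) per survey
year and flags any state/age cell whose range across years exceeds a
10-percentage-point band — an automated stand-in for assessing trends
visually. Cells with fewer than 25 usable respondents are reported as
missing rather than allowed to generate noise-driven flags.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data with fixed seeds, at sizes
chosen to keep the full suite within a desktop coffee break:

* oracle equivalence of the matrix-product interval probability against
  exhaustive path enumeration at ≤ 6 steps, to 1e-12;
* row-stochasticity of step matrices to 1e-12; LE ≡ ΣE to 1e-10;
* the binomial closed form for a pure death model and the fundamental
  matrix $N = (I-Q)^{-1}$ closed form (tolerance half a step) for
  time-homogeneous expectancies;
* a 100-replicate recovery study at n = 2,000 persons × 14 waves: pooled
  95% Wald coverage of all 32 true parameters ≥ 90% (no single parameter
  below 85/100), per-parameter bias below half the estimator's sampling
  SD, and 95% expectancy intervals covering the true HWLE in ≥ 90/100
  replicates (400 draws per replicate);
* one end-to-end run at n = 5,000 from raw answers through preparation,
  fitting and expectancies, recovering the true HWLE within two standard
  errors;
* a deterministic directional check that raising every exit from the
  healthy-working state strictly lowers HWLE, and a three-replicate
  stratified version with a strong injected arthritis effect.

Numerical details worth knowing: softmax rows are computed with a
log-sum-exp guard, so `-Inf` logits are exact structural zeros; the
likelihood returns `+Inf` (never `NaN`) on probability underflow;
`-2`-coded rows are dropped before packing; duplicate interview dates and
deaths not after the last interview are errors, not guesses. The horizon
default (60 years) leaves ~1e-11 living occupancy under the default truth.

## Known limitations

* Stratified refits treat strata as independent; no shrinkage or joint
  model across table rows.
* The anchor prevalence resampling uses effective multinomial counts,
  ignoring survey design effects (exact for the constant-weight synthetic
  cohort).
* A cohort whose unknown-state waves all precede the first known state
  contributes nothing; with an entry-state distribution model they could.
* Expectancies are truncated at the horizon (with a residual-occupancy
  check) rather than closed out analytically.
* The time-varying covariate path within an interval is frozen at its
  origin value, as in the pooled-fit convention; a half-step change point
  would be an alternative the data cannot distinguish at biennial spacing.
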
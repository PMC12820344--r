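test_that("descriptive counts match a hand-computed three-person fixture", {
  panel <- make_panel(list(
    list(date = c("2000-01", "2002-01"), age = c(55, 57), state = c(1, 2),
         weight = 2, arthritis = c(0L, 1L)),
    list(date = "2000-01", age = 60, state = 3, weight = 1),
    list(date = "2000-01", age = 62, state = 4, weight = 1)))
  panel$sex_female <- ifelse(panel$id == 1, 1L, 0L)
  tab <- descriptive_table(panel)
  fem <- tab[tab$variable == "sex" & tab$level == "female", ]
  expect_equal(fem$n, 1L)
  expect_equal(fem$pct, 33.3)
  expect_equal(fem$weighted_n, 2)
  expect_equal(fem$weighted_pct, 50)
  arth <- tab[tab$variable == "arthritis_ever" & tab$level == "yes", ]
  expect_equal(arth$n, 1L)  # ever-arthritis: person 1 reports at wave 2
  obese_no <- tab[tab$variable == "obese_ever" & tab$level == "no", ]
  expect_equal(obese_no$n, 3L)
})

test_that("time-varying splitting classifies transitions by origin value", {
  panel <- make_panel(list(
    list(date = c("2000-01", "2002-01", "2004-01"), age = c(55, 57, 59),
         state = c(1, 2, 4), arthritis = c(0L, 1L, 1L),
         death_date = "2005-06")))
  sp <- hwle:::split_timevarying(panel, "arthritis")
  expect_equal(length(unique(sp$id)), 2L)
  runs <- split(sp, sp$id)
  # run 1: arthritis 0, one wave, death date removed
  expect_equal(nrow(runs[[1]]), 1L)
  expect_equal(runs[[1]]$death_date, "")
  # run 2: arthritis 1, two waves, keeps the death date
  expect_equal(nrow(runs[[2]]), 2L)
  expect_equal(unique(runs[[2]]$death_date), "2005-06")
})

test_that("identical generating parameters give a null arthritis contrast", {
  # arthritis does not enter the truth: stratified estimates must agree
  cfg <- true_model_config(n_individuals = 2500, seed = 101)
  panel <- generate_cohort(cfg)$panel
  study <- suppressWarnings(run_stratified_analysis(
    panel, strata = list("arthritis"), n_draws = 300, seed = 1))
  tab <- study$table
  expect_equal(nrow(tab), 2L)
  diff <- abs(tab$hwle[1] - tab$hwle[2])
  pooled_se <- sqrt(sum(tab$hwle_se^2))
  expect_lt(diff, 2 * pooled_se)
  # every emitted row satisfies the sum identity
  expect_lt(max(abs(tab$e1 + tab$e2 + tab$e3 + tab$e4 - tab$le)), 1e-8)
})

test_that("arthritis that raises exits from state 1 lowers estimated HWLE", {
  s <- transition_structure(covariates = "arthritis")
  truth <- default_true_params(s)
  for (to in c(2, 3, 4)) {
    truth <- set_par(truth, s, 1, to, arthritis = 0.9)
  }
  wins <- 0L
  for (r in 1:3) {
    cfg <- true_model_config(
      n_individuals = 1500, seed = 300 + r, structure = s,
      transition_params = truth, n_waves = 10)
    panel <- generate_cohort(cfg)$panel
    study <- suppressWarnings(run_stratified_analysis(
      panel, strata = list("arthritis"), n_draws = 100, seed = r))
    tab <- study$table
    h_no <- tab$hwle[tab$stratum == "arthritis=0"]
    h_yes <- tab$hwle[tab$stratum == "arthritis=1"]
    if (length(h_no) == 1 && length(h_yes) == 1 && h_yes < h_no) {
      wins <- wins + 1L
    }
  }
  expect_equal(wins, 3L)
})

test_that("undersized strata are skipped with a diagnostic, not an error", {
  cfg <- true_model_config(n_individuals = 300, seed = 103, n_waves = 6)
  panel <- generate_cohort(cfg)$panel
  panel$ethnicity[panel$id <= 295] <- "white"
  panel$ethnicity[panel$id > 295] <- "black"
  study <- suppressWarnings(run_stratified_analysis(
    panel, strata = list("ethnicity"), n_draws = 100, seed = 2,
    min_persons = 50))
  expect_true(any(grepl("skipped", study$log)))
  expect_false("ethnicity=black" %in% study$table$stratum)
})

test_that("a stationary cohort is flagged stable across calendar years", {
  # stationarity by construction: age-homogeneous transitions started from
  # the quasi-stationary distribution of the living block, so the state mix
  # conditional on survival is the same at every age and calendar year
  s <- transition_structure(include_age = FALSE)
  p <- default_true_params(s)  # intercepts only: age-homogeneous chain
  Q <- step_transition_matrix(50, p, s)[1:4, 1:4]
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  v <- v / sum(v)
  cfg <- true_model_config(n_individuals = 8000, seed = 104, structure = s,
                           transition_params = p, initial_state_probs = v)
  panel <- generate_cohort(cfg)$panel
  sens <- sensitivity_prevalence_by_wave(panel, age_window = 2)
  expect_equal(sens$flag, "stable")
  expect_true(all(sens$ranges$flag == "stable"))
  expect_setequal(unique(sens$prevalence$age), c(55, 60, 65))
})

test_that("an injected calendar drift is flagged as a trend", {
  cfg <- true_model_config(n_individuals = 4000, seed = 105)
  panel <- generate_cohort(cfg)$panel
  # construct a counterexample: relabel states so that later survey years
  # have far more not-working respondents at the target ages
  yr <- as.integer(substr(panel$date, 1, 4))
  late <- yr >= 2008 & panel$state %in% c(1, 3)
  drift <- panel
  drift$state[late] <- ifelse(drift$state[late] == 1, 2L, 4L)
  sens <- sensitivity_prevalence_by_wave(drift)
  expect_equal(sens$flag, "trend")
})

test_that("a single-year panel yields one column and no flags", {
  cfg <- true_model_config(n_individuals = 500, seed = 106, n_waves = 1,
                           wave_spacing = 12, entry_age_range = c(54, 66))
  panel <- generate_cohort(cfg)$panel
  sens <- sensitivity_prevalence_by_wave(panel)
  expect_null(sens$ranges)
  expect_true(is.na(sens$flag))
  expect_equal(length(unique(sens$prevalence$year)), 1L)
})
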
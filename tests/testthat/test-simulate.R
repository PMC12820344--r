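test_that("generation is deterministic given the seed", {
  cfg <- true_model_config(n_individuals = 80, seed = 123, n_waves = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$states, b$truth$states)
  cfg2 <- true_model_config(n_individuals = 80, seed = 124, n_waves = 5)
  expect_false(identical(generate_cohort(cfg2)$panel, a$panel))
})

test_that("structural zeros freeze everyone in their initial state", {
  cfg <- true_model_config(
    n_individuals = 60, seed = 2, n_waves = 4,
    transition_params = init_params(transition_structure(),
                                    intercept = -Inf),
    missing_state_rate = 0, skipped_wave_rate = 0)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$states == co$truth$states[, 1]))
  per <- split(co$panel$state, co$panel$id)
  expect_true(all(vapply(per, function(s) all(s == s[1]), logical(1))))
})

test_that("constant death hazard reproduces the two-step death fraction", {
  # per-step death probability 0.1 from every living state, no other moves
  s <- transition_structure(
    permitted = cbind(1:4, 5), include_age = FALSE)
  p <- init_params(s, intercept = log(0.1 / 0.9))
  cfg <- true_model_config(
    n_individuals = 10000, seed = 99, n_waves = 2, wave_spacing = 24,
    structure = s, transition_params = p,
    missing_state_rate = 0, skipped_wave_rate = 0)
  co <- generate_cohort(cfg)
  dead2 <- mean(co$truth$states[, 3] == 5)
  # binomial oracle: 1 - 0.9^2 = 0.19, 99.9% CI half-width
  ci <- 3.29 * sqrt(0.19 * 0.81 / 10000)
  expect_lt(abs(dead2 - 0.19), ci)
})

test_that("empirical one-step transitions converge to the truth matrices", {
  s <- full_structure
  truth <- default_true_params(s)
  cfg <- true_model_config(n_individuals = 4000, seed = 31, n_waves = 8,
                           entry_age_range = c(55, 55.084),
                           missing_state_rate = 0, skipped_wave_rate = 0)
  co <- generate_cohort(cfg)
  S <- co$truth$states
  # everyone enters at (essentially) 55: pool the first simulated step
  M <- step_transition_matrix(55, truth, s,
                              covariates = NULL)
  for (i in 1:4) {
    sel <- S[, 1] == i
    n_i <- sum(sel)
    for (j in 1:5) {
      phat <- mean(S[sel, 2] == j)
      se <- sqrt(max(M[i, j] * (1 - M[i, j]), 1e-6) / n_i)
      expect_lt(abs(phat - M[i, j]), 3.3 * se + 1e-9)
    }
  }
})

test_that("death is absorbing and age-specific mortality increases", {
  cfg <- true_model_config(n_individuals = 3000, seed = 17)
  co <- generate_cohort(cfg)
  S <- co$truth$states
  dead <- S == 5
  expect_true(all(dead[, -ncol(dead)] <= dead[, -1]))
  # arthritis is monotone along the path
  A <- co$truth$arthritis
  expect_true(all(A[, -ncol(A)] <= A[, -1]))
  # positive death-logit age slope: later-step mortality hazard is higher
  alive_early <- S[, 1] <= 4
  died_early <- S[, 3] == 5 & alive_early
  alive_late <- S[, 11] <= 4
  died_late <- S[, 13] == 5 & alive_late
  expect_gt(mean(died_late[alive_late]), mean(died_early[alive_early]))
})

test_that("observation dates increase and precede the death date", {
  cfg <- true_model_config(n_individuals = 300, seed = 4)
  panel <- generate_cohort(cfg)$panel
  for (d in split(panel, panel$id)) {
    m <- ym_parse(d$date)
    expect_true(all(diff(m) > 0))
    if (nzchar(d$death_date[1])) {
      expect_true(all(m < ym_parse(d$death_date[1])))
    }
  }
})

test_that("missingness rates are honoured and death dates untouched", {
  cfg <- true_model_config(n_individuals = 1500, seed = 55,
                           missing_state_rate = 0, skipped_wave_rate = 0)
  co <- generate_cohort(cfg)
  base <- co$panel
  # zero rates leave the cohort unchanged
  expect_identical(inject_missingness(co, 0, 0)$panel, base)
  # rate one converts every participated wave to -1, vital status intact
  all1 <- inject_missingness(co, 1, 0, seed = 1)$panel
  expect_true(all(all1$state == -1))
  expect_identical(all1$death_date, base$death_date)
  # moderate rates: observed fractions within 99.9% binomial intervals
  inj <- inject_missingness(co, 0.1, 0.1, seed = 2)$panel
  n <- nrow(base)
  f2 <- mean(inj$state == -2)
  # -2 skips protect the last wave of decedents, so compare against the
  # eligible fraction
  has_death <- nzchar(base$death_date)
  last_row <- !duplicated(base$id, fromLast = TRUE)
  elig <- mean(!(has_death & last_row))
  expect_lt(abs(f2 - 0.1 * elig), 3.3 * sqrt(0.1 * 0.9 / n) + 1e-9)
  f1 <- mean(inj$state == -1)
  expect_lt(abs(f1 - 0.1 * (1 - f2)), 3.3 * sqrt(0.1 * 0.9 / n) + 1e-9)
  # the last wave of a decedent is never skipped
  expect_true(all(inj$state[has_death & last_row] != -2))
  expect_error(inject_missingness(co, 1.2, 0), "rates")
})

test_that("invalid configurations are rejected", {
  expect_error(true_model_config(n_individuals = 0), "n_individuals")
  expect_error(true_model_config(missing_state_rate = -0.1), "probabilities")
  expect_error(true_model_config(initial_state_probs = c(1, 1, 0, 0)),
               "sum to 1")
  expect_error(true_model_config(wave_spacing = 18, step_months = 12),
               "multiple")
})

test_that("a finer simulation grid leaves the observed process comparable", {
  s <- full_structure
  base <- true_model_config(n_individuals = 2500, seed = 61, n_waves = 4,
                            missing_state_rate = 0, skipped_wave_rate = 0)
  fine <- true_model_config(n_individuals = 2500, seed = 61, n_waves = 4,
                            sim_step_months = 1,
                            missing_state_rate = 0, skipped_wave_rate = 0)
  p12 <- generate_cohort(base)$panel
  p1 <- generate_cohort(fine)$panel
  # wave-4 survival under the monthly grid is close to the 12-month grid
  surv <- function(p) length(unique(p$id[p$wave == 4])) / 2500
  expect_lt(abs(surv(p12) - surv(p1)), 0.03)
})
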
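test_that("initial prevalence is the survey-weighted state distribution", {
  panel <- make_panel(list(
    list(date = "2000-01", age = 50.2, state = 1, weight = 2),
    list(date = "2000-01", age = 50.7, state = 4, weight = 1)))
  pr <- initial_prevalence(panel, 50, 1)
  expect_equal(pr$weights, c(2 / 3, 0, 0, 1 / 3))
  # single person: degenerate distribution
  pr1 <- initial_prevalence(panel[panel$id == 1, ], 50, 1)
  expect_equal(pr1$weights, c(1, 0, 0, 0))
  # unknown states and out-of-window ages are excluded
  panel2 <- rbind(panel, make_panel(list(
    list(date = "2000-01", age = 50.5, state = -1, weight = 10),
    list(date = "2000-01", age = 53, state = 2, weight = 10))))
  expect_equal(initial_prevalence(panel2, 50, 1)$weights, pr$weights)
  expect_error(initial_prevalence(panel, 80, 1), "widen the window")
})

test_that("cohort prevalence recovers the generator's initial distribution", {
  cfg <- true_model_config(n_individuals = 4000, seed = 81)
  panel <- generate_cohort(cfg)$panel
  pr <- initial_prevalence(panel, 50, 2)
  truth <- cfg$initial_state_probs
  for (i in 1:4) {
    se <- sqrt(truth[i] * (1 - truth[i]) / pr$n)
    expect_lt(abs(pr$weights[i] - truth[i]), 3 * se)
  }
})

test_that("with no exits and no mortality the expectancy is the horizon", {
  s <- transition_structure(permitted = cbind(1, 2))
  p <- init_params(s, intercept = -Inf)
  e <- suppressWarnings(
    conditional_state_expectancies(p, structure = s, horizon = 40))
  expect_equal(e[1, 1], 40)
  expect_equal(e[1, 2], 0)
})

test_that("time-homogeneous expectancies match the fundamental matrix", {
  # age slopes zero: closed form N = (I - Q)^-1, occupancy time h * (N - I/2)
  # under trapezoidal end-point correction
  s <- transition_structure(include_age = FALSE)
  set.seed(5)
  p <- init_params(s, intercept = -2.2) + stats::rnorm(16, 0, 0.4)
  # ensure nontrivial mortality so the chain absorbs within the horizon
  for (i in 1:4) p <- set_par(p, s, i, 5, a = -2.2)
  P <- step_transition_matrix(50, p, s)
  Q <- P[1:4, 1:4]
  N <- solve(diag(4) - Q)
  h <- s$step_months / 12
  closed <- h * (N - diag(4) / 2)
  e <- conditional_state_expectancies(p, structure = s, horizon = 200)
  expect_lt(max(abs(e - closed)), 0.5 * h)
})

test_that("raising mortality shrinks every row's total expectancy", {
  s <- full_structure
  p <- default_true_params(s)
  e0 <- conditional_state_expectancies(p, structure = s)
  p2 <- p
  for (i in 1:4) {
    p2 <- set_par(p2, s, i, 5, a = p[[sprintf("a[%d>D]", i)]] + 1)
  }
  e2 <- conditional_state_expectancies(p2, structure = s)
  expect_true(all(rowSums(e2) < rowSums(e0)))
})

test_that("population expectancies combine rows by the prevalence weights", {
  s <- full_structure
  e <- conditional_state_expectancies(default_true_params(s), structure = s)
  # degenerate weights select one row
  pe <- population_expectancies(e, c(1, 0, 0, 0))
  expect_equal(unname(pe$E), unname(e[1, ]))
  # equal rows make the population values weight invariant
  eq <- matrix(rep(c(4, 3, 2, 1), each = 4), 4)
  w1 <- population_expectancies(eq, c(0.25, 0.25, 0.25, 0.25))
  w2 <- population_expectancies(eq, c(0.7, 0.1, 0.1, 0.1))
  expect_equal(w1$E, w2$E)
  # life expectancy is the sum of the four expectancies by construction
  pe2 <- population_expectancies(e, c(0.4, 0.3, 0.2, 0.1))
  expect_lt(abs(pe2$LE - sum(pe2$E)), 1e-10)
  expect_lte(pe2$HWLE, pe2$LE)
})

test_that("model expectancies agree with simulated trajectories", {
  s <- full_structure
  p <- default_true_params(s)
  w <- c(0.55, 0.20, 0.10, 0.15)
  pe <- population_expectancies(
    conditional_state_expectancies(p, structure = s), w)
  set.seed(91)
  occ <- simulate_occupancy(p, s, 50000, init_probs = w)
  mc_se <- stats::sd(occ[, 1]) / sqrt(nrow(occ))
  expect_lt(abs(pe$HWLE - mean(occ[, 1])), 2 * mc_se)
  mc_se_le <- stats::sd(rowSums(occ)) / sqrt(nrow(occ))
  expect_lt(abs(pe$LE - mean(rowSums(occ))), 2 * mc_se_le)
})

test_that("halving the step length moves expectancies by less than 0.15 y", {
  s12 <- transition_structure(step_months = 12)
  s6 <- transition_structure(step_months = 6)
  p12 <- default_true_params(s12)
  # the six-month chain uses the half-step fractional matrices of the same
  # yearly model, so the comparison isolates the discretisation rule
  e12 <- conditional_state_expectancies(p12, structure = s12)
  e6 <- matrix(0, 4, 4)
  h <- 0.5
  U <- cbind(diag(4), rep(0, 4))
  for (k in seq_len(120) - 1L) {
    P <- step_transition_matrix(50 + k * h, p12, s12)
    Pf <- diag(5) * 0.5 + 0.5 * P
    U1 <- U %*% Pf
    e6 <- e6 + 0.5 * h * (U[, 1:4] + U1[, 1:4])
    U <- U1
  }
  pe12 <- population_expectancies(e12, c(0.55, 0.2, 0.1, 0.15))
  pe6 <- population_expectancies(e6, c(0.55, 0.2, 0.1, 0.15))
  expect_lt(max(abs(pe12$E - pe6$E)), 0.15)
})

test_that("zero covariance gives zero-width intervals, scaling doubles SEs", {
  s <- full_structure
  p <- default_true_params(s)
  fit0 <- base::structure(
    list(coefficients = p, vcov = matrix(0, 32, 32), logLik = 0,
         convergence = list(converged = TRUE), structure = s),
    class = "hwle_fit")
  w <- c(0.55, 0.2, 0.1, 0.15)
  ci0 <- confidence_intervals(fit0, w, n_draws = 50, seed = 1)
  expect_equal(unname(ci0$se), rep(0, 6))
  expect_equal(ci0$ci[1, "HWLE"], ci0$ci[2, "HWLE"])
  # small diagonal covariance shaped like a real fit (age-slope uncertainty
  # an order of magnitude tighter than intercepts, keeping the mapping in
  # its linear regime): quadrupling variances doubles the SEs
  v <- diag(rep(c(1e-4, 1e-6), 16))
  fit1 <- fit0; fit1$vcov <- v
  fit4 <- fit0; fit4$vcov <- 4 * v
  ci1 <- confidence_intervals(fit1, w, n_draws = 2000, seed = 2)
  ci4 <- confidence_intervals(fit4, w, n_draws = 2000, seed = 2)
  expect_lt(max(abs(ci4$se / ci1$se - 2)), 0.4)  # 20% on the ratio of 2
})

test_that("missing covariance yields point estimates without intervals", {
  s <- full_structure
  fit <- base::structure(
    list(coefficients = default_true_params(s), vcov = NULL, logLik = 0,
         convergence = list(converged = TRUE), structure = s),
    class = "hwle_fit")
  ci <- confidence_intervals(fit, c(0.55, 0.2, 0.1, 0.15))
  expect_false(ci$available)
  expect_gt(ci$point$HWLE, 0)
})

test_that("percentage of life expectancy matches the published arithmetic", {
  expect_identical(percent_of_le(6.10, 27.91), 22L)
  expect_identical(percent_of_le(12.36, 30.18), 41L)
  expect_identical(percent_of_le(5, 10), 50L)
  expect_identical(percent_of_le(2.5, 100), 3L)  # half away from zero
  expect_error(percent_of_le(5, 0), "positive")
})

test_that("working-days-lost arithmetic matches the published example", {
  expect_equal(working_days_lost(11.71, 6.18), 1437.8)
  expect_equal(working_days_lost(11.71, 6.18, round_hundreds = TRUE), 1400)
  expect_equal(working_days_lost(4, 4), 0)
  expect_equal(working_days_lost(10, 9, 100), 100)
  expect_error(working_days_lost(10, 9, 0), "positive")
})
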
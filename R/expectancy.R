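# Health expectancies from a fitted transition model.
#
# Conditional expectancies propagate occupancy vectors from each living
# starting state at the anchor age by repeated step-matrix multiplication,
# integrating occupancy with the trapezoidal rule. Population expectancies
# weight the starting states by the survey-weighted observed prevalence at
# the anchor age; life expectancy is the sum of the four state expectancies
# by construction.

#' Survey-weighted initial prevalence of the living states
#'
#' @param panel coded panel data.frame.
#' @param age_anchor anchor age in years (default 50).
#' @param window width in years of the age window `[age_anchor,
#'   age_anchor + window)` (default 1). Observations with unknown state are
#'   excluded from numerator and denominator.
#' @return object of class `hwle_prevalence`: list with `weights` (length-4,
#'   summing to 1), `n` (observations used), `age_anchor`, `window`.
#' @export
initial_prevalence <- function(panel, age_anchor = 50, window = 1) {
  check_panel(panel)
  sel <- panel$state %in% 1:4 & !is.na(panel$age) &
    panel$age >= age_anchor & panel$age < age_anchor + window &
    panel$weight > 0
  if (!any(sel)) {
    stop("no usable observations in [", age_anchor, ", ",
         age_anchor + window, "); widen the window (refreshment entry ages ",
         "may not cover the anchor age exactly)")
  }
  w <- vapply(1:4, function(s) {
    sum(panel$weight[sel & panel$state == s])
  }, numeric(1))
  structure(list(weights = w / sum(w), n = sum(sel),
                 age_anchor = age_anchor, window = window),
            class = "hwle_prevalence")
}

# fast path: conditional expectancies directly from a parameter vector
cond_expectancies_par <- function(params, structure, age_anchor = 50,
                                  horizon = 60, covariates = NULL,
                                  check_residual = FALSE) {
  h <- structure$step_months / 12
  nfull <- floor(horizon / h + 1e-9)
  frac <- horizon / h - nfull
  if (frac < 1e-9) frac <- 0
  U <- cbind(diag(4), rep(0, 4))   # rows: starting state; cols: 5 states
  e <- matrix(0, 4, 4, dimnames = list(paste0("from", 1:4), paste0("in", 1:4)))
  for (k in seq_len(nfull) - 1L) {
    M <- step_transition_matrix(age_anchor + k * h, params, structure,
                                covariates)
    U1 <- U %*% M
    e <- e + 0.5 * h * (U[, 1:4] + U1[, 1:4])
    U <- U1
  }
  if (frac > 0) {
    M <- fractional_step(
      step_transition_matrix(age_anchor + nfull * h, params, structure,
                             covariates), frac)
    U1 <- U %*% M
    e <- e + 0.5 * frac * h * (U[, 1:4] + U1[, 1:4])
    U <- U1
  }
  if (check_residual) {
    resid <- max(rowSums(U[, 1:4]))
    if (resid > 1e-4) {
      warning(sprintf(
        "living occupancy %.2g remains at the %g-year horizon; expectancies are truncated",
        resid, horizon))
    }
  }
  e
}

#' Conditional state expectancies by starting state
#'
#' Expected years spent in each living state between the anchor age and the
#' horizon, for each living starting state at the anchor age.
#'
#' @param fitted an `hwle_fit` (or a parameter vector, with `structure`
#'   supplied).
#' @param age_anchor anchor age (default 50).
#' @param horizon years of follow-up integrated (default 60, i.e. to age
#'   110; a warning is raised if living occupancy above 1e-4 remains).
#' @param covariates named covariate values when the model has covariates.
#' @param structure required when `fitted` is a bare parameter vector.
#' @return 4 x 4 matrix `e[i, j]` = expected years in state `j` starting
#'   from state `i`.
#' @export
conditional_state_expectancies <- function(fitted, age_anchor = 50,
                                           horizon = 60, covariates = NULL,
                                           structure = NULL) {
  if (inherits(fitted, "hwle_fit")) {
    params <- fitted$coefficients
    structure <- fitted$structure
  } else {
    params <- fitted
    if (is.null(structure)) stop("supply a structure with a bare parameter vector")
  }
  cond_expectancies_par(params, structure, age_anchor, horizon, covariates,
                        check_residual = TRUE)
}

#' Prevalence-weighted population expectancies
#'
#' Averages the conditional expectancies over starting states with the
#' observed prevalence weights. `HWLE` is the expectancy of state 1 (healthy
#' and working); life expectancy is the sum of the four state expectancies.
#'
#' @param e 4 x 4 conditional expectancy matrix.
#' @param weights an `hwle_prevalence` or a length-4 non-negative vector
#'   summing to 1.
#' @return object of class `hwle_expectancy`: list with `E` (four population
#'   expectancies), `HWLE`, `LE`, `e`, `weights`.
#' @export
population_expectancies <- function(e, weights) {
  if (inherits(weights, "hwle_prevalence")) weights <- weights$weights
  stopifnot(length(weights) == 4, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("prevalence weights must sum to 1")
  if (any(e < 0)) stop("negative conditional expectancy")
  E <- as.numeric(weights %*% e)
  names(E) <- c("healthy_working", "healthy_not_working",
                "not_healthy_working", "not_healthy_not_working")
  structure(list(E = E, HWLE = E[[1]], LE = sum(E), e = e,
                 weights = weights),
            class = "hwle_expectancy")
}

#' @export
print.hwle_expectancy <- function(x, ...) {
  cat("Population health expectancies (years from anchor age)\n")
  for (nm in names(x$E)) cat(sprintf("  %-26s %6.2f\n", nm, x$E[[nm]]))
  cat(sprintf("  %-26s %6.2f\n", "life expectancy (sum)", x$LE))
  cat(sprintf("  HWLE share of LE: %d%%\n", percent_of_le(x$HWLE, x$LE)))
  invisible(x)
}

#' Parametric-simulation standard errors and confidence intervals
#'
#' Draws parameter vectors from the multivariate normal distribution of the
#' estimates, recomputes all expectancies for each draw, and reports draw
#' standard deviations as SEs with 2.5/97.5 percentile intervals.
#' Deterministic given `seed`.
#'
#' When `weights` is an [initial_prevalence()] result the anchor-age state
#' distribution is itself an estimate, so each draw also resamples the
#' prevalence weights (Dirichlet with the observed effective counts); the
#' intervals then cover both parameter and anchor-prevalence uncertainty.
#' Passing a bare length-4 vector treats the weights as known and the
#' intervals reflect parameter uncertainty only.
#'
#' @param fitted an `hwle_fit` with an available covariance.
#' @param weights an `hwle_prevalence` or length-4 weight vector.
#' @param n_draws number of parameter draws (default 1000).
#' @param seed RNG seed.
#' @param age_anchor,horizon,covariates passed to the expectancy pipeline.
#' @return object of class `hwle_expectancy_ci`: the point
#'   `hwle_expectancy` plus `se` and `ci` (2 x k matrix) for the four
#'   expectancies, HWLE and LE; `available = FALSE` (point estimates only)
#'   when the covariance is unavailable.
#' @export
confidence_intervals <- function(fitted, weights, n_draws = 1000,
                                 seed = NULL, age_anchor = 50, horizon = 60,
                                 covariates = NULL) {
  stopifnot(inherits(fitted, "hwle_fit"))
  prev_alpha <- NULL
  if (inherits(weights, "hwle_prevalence")) {
    prev_alpha <- weights$weights * weights$n  # effective multinomial counts
    weights <- weights$weights
  }
  point <- population_expectancies(
    cond_expectancies_par(fitted$coefficients, fitted$structure, age_anchor,
                          horizon, covariates), weights)
  if (is.null(fitted$vcov)) {
    return(structure(list(point = point, se = NULL, ci = NULL,
                          available = FALSE, n_draws = 0),
                     class = "hwle_expectancy_ci"))
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, fitted$coefficients, fitted$vcov)
  if (n_draws == 1) draws <- matrix(draws, nrow = 1)
  qty <- matrix(NA_real_, n_draws, 6,
                dimnames = list(NULL, c(names(point$E), "HWLE", "LE")))
  for (d in seq_len(n_draws)) {
    e <- cond_expectancies_par(draws[d, ], fitted$structure, age_anchor,
                               horizon, covariates)
    wd <- weights
    if (!is.null(prev_alpha)) {
      g <- stats::rgamma(4, shape = prev_alpha)
      if (sum(g) > 0) wd <- g / sum(g)
    }
    E <- as.numeric(wd %*% e)
    qty[d, ] <- c(E, E[1], sum(E))
  }
  se <- apply(qty, 2, stats::sd)
  ci <- apply(qty, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(point = point, se = se, ci = ci, available = TRUE,
                 n_draws = n_draws),
            class = "hwle_expectancy_ci")
}

#' @export
print.hwle_expectancy_ci <- function(x, ...) {
  print(x$point)
  if (!x$available) {
    cat("  (confidence intervals unavailable: no covariance)\n")
    return(invisible(x))
  }
  cat(sprintf("  HWLE 95%% CI: %.2f-%.2f; LE 95%% CI: %.2f-%.2f (%d draws)\n",
              x$ci[1, "HWLE"], x$ci[2, "HWLE"], x$ci[1, "LE"],
              x$ci[2, "LE"], x$n_draws))
  invisible(x)
}

#' HWLE as an integer percentage of life expectancy
#'
#' @param hwle,le expectancies in years (`le > 0`).
#' @return integer percent, rounded half away from zero.
#' @export
#' @examples
#' percent_of_le(6.10, 27.91)  # 22
percent_of_le <- function(hwle, le) {
  if (any(le <= 0)) stop("life expectancy must be positive")
  as.integer(round_half_away(100 * hwle / le))
}

#' Working days lost between two HWLE values
#'
#' @param hwle_ref,hwle_cmp reference and comparison HWLE in years.
#' @param working_days_per_year days per working year (default 260).
#' @param round_hundreds report rounded to the nearest hundred days.
#' @return days (difference times working days per year).
#' @export
#' @examples
#' working_days_lost(11.71, 6.18)                        # 1437.8
#' working_days_lost(11.71, 6.18, round_hundreds = TRUE) # 1400
working_days_lost <- function(hwle_ref, hwle_cmp, working_days_per_year = 260,
                              round_hundreds = FALSE) {
  if (working_days_per_year <= 0) stop("working_days_per_year must be positive")
  d <- (hwle_ref - hwle_cmp) * working_days_per_year
  if (round_hundreds) round_half_away(d / 100) * 100 else d
}
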
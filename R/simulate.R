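# Synthetic cohort generator.
#
# Emulates a biennial panel survey of a five-state monthly-resolution health
# and work process: refreshment entry ages, age-increasing mortality and
# morbidity, irreversible arthritis, obesity as a time-varying binary,
# survey weights, month-resolution death dates, and the two missingness
# codes (-1 alive/state unknown, -2 wave not participated). Every downstream
# stage is testable against the generator's known ground truth.

#' Ground-truth transition parameters of the default synthetic cohort
#'
#' Age-adjusted logits (intercept at age 50, slope per year) for the full
#' 16-transition structure, chosen once to give a plausible population from
#' age 50: exits from the healthy-and-working state dominated by leaving work
#' with age, declining return-to-work rates, and Gompertz-like mortality
#' (log-hazard slope 0.09/year). Under these values, with the default
#' initial state distribution, HWLE from age 50 is about 9.2 years and life
#' expectancy about 30.7 years.
#'
#' @param structure the [transition_structure()] the parameters must respect
#'   (extra covariate coefficients default to 0).
#' @return named parameter vector.
#' @export
default_true_params <- function(structure = transition_structure()) {
  p <- init_params(structure)
  tab <- rbind(
    # from to     a      b
    c(1, 2, -3.40,  0.120),
    c(1, 3, -3.80,  0.030),
    c(1, 4, -4.80,  0.050),
    c(1, 5, -7.00,  0.090),
    c(2, 1, -1.40, -0.110),
    c(2, 3, -4.60,  0.020),
    c(2, 4, -3.40,  0.050),
    c(2, 5, -6.40,  0.090),
    c(3, 1, -1.30, -0.050),
    c(3, 2, -4.00,  0.060),
    c(3, 4, -2.40,  0.060),
    c(3, 5, -5.80,  0.090),
    c(4, 1, -3.00, -0.080),
    c(4, 2, -2.80, -0.020),
    c(4, 3, -2.90, -0.050),
    c(4, 5, -4.65,  0.090)
  )
  for (r in seq_len(nrow(tab))) {
    if (any(structure$pairs[, "from"] == tab[r, 1] &
            structure$pairs[, "to"] == tab[r, 2])) {
      p <- set_par(p, structure, tab[r, 1], tab[r, 2],
                   a = tab[r, 3],
                   b = if (structure$include_age) tab[r, 4] else NULL)
    }
  }
  p
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults are the study conditions emulated throughout the package:
#' 14 biennial waves, 12-month interpolation steps, refreshment entry ages
#' uniform over 50-60, covariate prevalences matching a large US survey of
#' older adults, and moderate unknown-state/skipped-wave missingness.
#'
#' @param n_individuals number of persons.
#' @param seed RNG seed used by [generate_cohort()].
#' @param entry_age_range numeric length-2, entry ages are uniform (at month
#'   resolution) over this interval.
#' @param n_waves number of survey waves.
#' @param wave_spacing months between waves (default 24).
#' @param step_months estimator interpolation step (default 12).
#' @param sim_step_months simulation grid (default equals `step_months`; a
#'   finer grid, e.g. 1 month, simulates fractional-step dynamics
#'   `P_f = (1-f)I + fP` and is used to probe discretisation bias).
#' @param structure transition structure of the ground truth (its covariates
#'   must be among `arthritis`, `obese`, `sex_female`, `educ_hs`).
#' @param transition_params ground-truth parameter vector.
#' @param initial_state_probs length-4 probabilities of the living states at
#'   entry.
#' @param covariate_prevalences list with elements `female`, `education`
#'   (high-school share), `ethnicity` (named probabilities), `region` (named
#'   probabilities), `obese` (baseline), `arthritis` (baseline).
#' @param arthritis_onset_hazard per-step onset probability; scalar or
#'   `function(age)`.
#' @param obesity_flip_prob per-step probability that obesity status toggles.
#' @param missing_state_rate probability a participated wave is recorded with
#'   unknown state (-1).
#' @param skipped_wave_rate probability a wave is missed entirely (-2).
#' @param weight_distribution `NULL` for constant weight 1, or `function(n)`
#'   returning positive survey weights.
#' @param start_year calendar year of the first wave.
#' @return validated list of class `hwle_config`.
#' @export
true_model_config <- function(n_individuals = 2000,
                              seed = 1L,
                              entry_age_range = c(50, 60),
                              n_waves = 14,
                              wave_spacing = 24,
                              step_months = 12,
                              sim_step_months = step_months,
                              structure = transition_structure(
                                step_months = step_months),
                              transition_params = default_true_params(structure),
                              initial_state_probs = c(0.55, 0.20, 0.10, 0.15),
                              covariate_prevalences = list(
                                female = 0.55, education = 0.77,
                                ethnicity = c(black = 0.19, white = 0.72,
                                              other = 0.09),
                                region = c(Midwest = 0.23, Northeast = 0.17,
                                           South = 0.44, West = 0.16),
                                obese = 0.30, arthritis = 0.40),
                              arthritis_onset_hazard = 0.035,
                              obesity_flip_prob = 0,
                              missing_state_rate = 0.05,
                              skipped_wave_rate = 0.05,
                              weight_distribution = NULL,
                              start_year = 1994) {
  cfg <- list(n_individuals = n_individuals, seed = seed,
              entry_age_range = entry_age_range, n_waves = n_waves,
              wave_spacing = wave_spacing, step_months = step_months,
              sim_step_months = sim_step_months, structure = structure,
              transition_params = transition_params,
              initial_state_probs = initial_state_probs,
              covariate_prevalences = covariate_prevalences,
              arthritis_onset_hazard = arthritis_onset_hazard,
              obesity_flip_prob = obesity_flip_prob,
              missing_state_rate = missing_state_rate,
              skipped_wave_rate = skipped_wave_rate,
              weight_distribution = weight_distribution,
              start_year = start_year)
  validate_config(cfg)
  class(cfg) <- "hwle_config"
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n_individuals) || cfg$n_individuals < 1) {
    stop("configuration error: n_individuals must be >= 1")
  }
  if (cfg$n_waves < 1 || cfg$wave_spacing <= 0 || cfg$step_months <= 0 ||
      cfg$sim_step_months <= 0) {
    stop("configuration error: counts and spacings must be positive")
  }
  if (cfg$wave_spacing %% cfg$sim_step_months != 0) {
    stop("configuration error: wave_spacing must be a multiple of the ",
         "simulation step")
  }
  probs <- c(cfg$initial_state_probs, cfg$missing_state_rate,
             cfg$skipped_wave_rate, cfg$obesity_flip_prob,
             cfg$covariate_prevalences$female,
             cfg$covariate_prevalences$education,
             cfg$covariate_prevalences$obese,
             cfg$covariate_prevalences$arthritis,
             cfg$covariate_prevalences$ethnicity,
             cfg$covariate_prevalences$region)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$initial_state_probs) - 1) > 1e-8) {
    stop("configuration error: initial_state_probs must sum to 1")
  }
  if (length(cfg$transition_params) != cfg$structure$n_par) {
    stop("configuration error: transition_params does not match structure")
  }
  unknown <- setdiff(cfg$structure$covariates,
                     c("arthritis", "obese", "sex_female", "educ_hs"))
  if (length(unknown)) {
    stop("configuration error: simulator cannot drive covariate(s) ",
         paste(unknown, collapse = ", "))
  }
  invisible(cfg)
}

# vectorised one-step advance of living individuals; returns next states
advance_states <- function(states, t_centred, covs, params, struct, frac) {
  n <- length(states)
  npp <- struct$n_par_per_pair
  idx0 <- (seq_len(struct$n_pairs) - 1L) * npp
  a <- params[idx0 + 1L]
  b <- if (struct$include_age) params[idx0 + 2L] else rep(0, struct$n_pairs)
  eta <- matrix(rep(a, each = n), n) + outer(t_centred, b)
  ncov <- length(struct$covariates)
  if (ncov) {
    base <- 1L + as.integer(struct$include_age)
    for (j in seq_len(ncov)) {
      cj <- params[idx0 + base + j]
      eta <- eta + outer(covs[[struct$covariates[j]]], cj)
    }
  }
  # per-individual row of its current state: up to 4 exit columns
  pair_of <- lapply(1:4, function(i) which(struct$pairs[, "from"] == i))
  pnext <- matrix(0, n, 5)
  pself <- numeric(n)
  for (i in 1:4) {
    rows <- which(states == i)
    if (!length(rows)) next
    cols <- pair_of[[i]]
    e <- eta[rows, cols, drop = FALSE]
    m <- pmax(0, apply(e, 1, max))
    ez <- exp(e - m)
    z <- exp(-m) + rowSums(ez)
    pnext[rows, struct$pairs[cols, "to"]] <- ez / z
    pself[rows] <- exp(-m) / z
  }
  sel <- cbind(seq_len(n), states)
  pnext[sel] <- pnext[sel] + pself
  if (frac < 1) {                    # P_f = (1-f) I + f P
    pnext <- frac * pnext
    pnext[sel] <- pnext[sel] + (1 - frac)
  }
  u <- stats::runif(n)
  c1 <- pnext[, 1]
  c2 <- c1 + pnext[, 2]
  c3 <- c2 + pnext[, 3]
  c4 <- c3 + pnext[, 4]
  as.integer(1L + (u > c1) + (u > c2) + (u > c3) + (u > c4))
}

#' Generate a synthetic cohort from a known five-state process
#'
#' Simulates each individual's complete state path step by step from the
#' ground-truth step transition matrices evaluated at the individual's age
#' and covariates, observes the true state at the biennial interview dates,
#' and then injects missingness (see [inject_missingness()]). Deterministic
#' given `config$seed`.
#'
#' @param config a [true_model_config()].
#' @param emit `"states"` emits coded states directly (the analysis-ready
#'   dialect); `"answers"` emits raw survey answers (limitation questions,
#'   employment item, arthritis diagnosis, height/weight, US state of
#'   residence) to exercise the panel-coding rules.
#' @return an object of class `hwle_cohort`: list with `panel` (long
#'   data.frame, one row per person-wave), `truth` (states on the simulation
#'   grid, death months, entry data, the configuration) and `structure`.
#' @export
generate_cohort <- function(config, emit = c("states", "answers")) {
  validate_config(config)
  emit <- match.arg(emit)
  set.seed(config$seed)
  n <- as.integer(config$n_individuals)
  struct <- config$structure
  params <- config$transition_params
  prev <- config$covariate_prevalences
  hsim <- config$sim_step_months / 12
  frac <- config$sim_step_months / config$step_months
  if (frac > 1) stop("simulation grid coarser than the estimator step")
  steps_per_wave <- config$wave_spacing %/% config$sim_step_months
  K <- (config$n_waves - 1L) * steps_per_wave

  start_m <- config$start_year * 12L
  entry_off <- sample.int(config$wave_spacing, n, replace = TRUE) - 1L
  entry_ym <- start_m + entry_off
  ea <- config$entry_age_range
  entry_age_months <- floor(ea[1] * 12) +
    sample.int(max(1L, floor((ea[2] - ea[1]) * 12)), n, replace = TRUE) - 1L
  birth_ym <- entry_ym - entry_age_months
  age_entry <- ym_age(birth_ym, entry_ym)

  sex_female <- stats::rbinom(n, 1, prev$female)
  educ_hs <- stats::rbinom(n, 1, prev$education)
  ethnicity <- sample(names(prev$ethnicity), n, replace = TRUE,
                      prob = prev$ethnicity)
  region <- sample(names(prev$region), n, replace = TRUE, prob = prev$region)
  weight <- if (is.null(config$weight_distribution)) rep(1, n) else {
    w <- config$weight_distribution(n)
    if (any(w <= 0)) stop("weight_distribution produced non-positive weights")
    w
  }

  S <- matrix(NA_integer_, n, K + 1L)
  A <- matrix(0L, n, K + 1L)
  O <- matrix(0L, n, K + 1L)
  S[, 1] <- sample.int(4L, n, replace = TRUE,
                       prob = config$initial_state_probs)
  A[, 1] <- stats::rbinom(n, 1, prev$arthritis)
  O[, 1] <- stats::rbinom(n, 1, prev$obese)
  onset <- config$arthritis_onset_hazard
  onset_fun <- if (is.function(onset)) onset else function(age) {
    rep(onset, length(age))
  }
  for (k in seq_len(K)) {
    alive <- which(S[, k] <= 4L)
    S[, k + 1L] <- S[, k]
    A[, k + 1L] <- A[, k]
    O[, k + 1L] <- O[, k]
    if (length(alive)) {
      age_k <- age_entry[alive] + (k - 1L) * hsim
      covs <- list(arthritis = A[alive, k], obese = O[alive, k],
                   sex_female = sex_female[alive], educ_hs = educ_hs[alive])
      S[alive, k + 1L] <- advance_states(S[alive, k],
                                         age_k - struct$age_center, covs,
                                         params, struct, frac)
      newly <- alive[A[alive, k] == 0L &
                       stats::runif(length(alive)) <
                         frac * onset_fun(age_k)]
      A[newly, k + 1L] <- 1L
      if (config$obesity_flip_prob > 0) {
        flip <- alive[stats::runif(length(alive)) <
                        frac * config$obesity_flip_prob]
        O[flip, k + 1L] <- 1L - O[flip, k]
      }
    }
  }
  # death month: end of the simulation step in which death occurred
  first_dead <- apply(S == 5L, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  death_ym <- entry_ym + (first_dead - 1L) * config$sim_step_months

  wave_cols <- 1L + (seq_len(config$n_waves) - 1L) * steps_per_wave
  rows <- list()
  for (w in seq_len(config$n_waves)) {
    jc <- wave_cols[w]
    obs_ym <- entry_ym + (w - 1L) * config$wave_spacing
    alive <- S[, jc] <= 4L
    if (!any(alive)) next
    i <- which(alive)
    rows[[w]] <- data.frame(
      id = i,
      wave = w,
      date = ym_format(obs_ym[i]),
      age = ym_age(birth_ym[i], obs_ym[i]),
      state = S[i, jc],
      arthritis = A[i, jc],
      obese = O[i, jc],
      sex_female = sex_female[i],
      educ_hs = educ_hs[i],
      ethnicity = ethnicity[i],
      region = region[i],
      weight = weight[i],
      birth_date = ym_format(birth_ym[i]),
      death_date = ym_format(death_ym[i]),
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  rownames(panel) <- NULL
  cohort <- structure(
    list(panel = panel,
         truth = list(config = config, states = S, arthritis = A, obese = O,
                      entry_ym = entry_ym, birth_ym = birth_ym,
                      death_ym = death_ym, age_entry = age_entry,
                      sex_female = sex_female, educ_hs = educ_hs,
                      ethnicity = ethnicity, region = region,
                      weight = weight),
         structure = struct),
    class = "hwle_cohort"
  )
  cohort <- inject_missingness(cohort, config$missing_state_rate,
                               config$skipped_wave_rate)
  if (emit == "answers") cohort$raw <- cohort_to_answers(cohort)
  cohort
}

#' Inject unknown-state and skipped-wave missingness into a cohort
#'
#' Flags participated waves as state `-1` (alive, state unknown) with
#' probability `missing_state_rate` and marks waves as skipped (`-2`,
#' unknown vital and health/work status, covariates not collected) with
#' probability `skipped_wave_rate`. Death dates are untouched, and the last
#' participated wave of an individual with a retained death date is never
#' converted to `-2`.
#'
#' @param cohort an `hwle_cohort` (or bare panel data.frame).
#' @param missing_state_rate,skipped_wave_rate probabilities in `[0, 1]`.
#' @param seed optional RNG seed; `NULL` continues the current stream.
#' @return object of the same type with missingness applied.
#' @export
inject_missingness <- function(cohort, missing_state_rate,
                               skipped_wave_rate, seed = NULL) {
  if (missing_state_rate < 0 || missing_state_rate > 1 ||
      skipped_wave_rate < 0 || skipped_wave_rate > 1) {
    stop("missingness rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  panel <- if (inherits(cohort, "hwle_cohort")) cohort$panel else cohort
  if (missing_state_rate == 0 && skipped_wave_rate == 0) return(cohort)
  n <- nrow(panel)
  participated <- panel$state %in% 1:4
  # -2: any wave except the last one of a person with a known death date
  has_death <- !is.na(panel$death_date) & nzchar(panel$death_date)
  last_row <- !duplicated(panel$id, fromLast = TRUE)
  eligible2 <- !(has_death & last_row)
  skip <- eligible2 & stats::runif(n) < skipped_wave_rate
  unk <- participated & !skip & stats::runif(n) < missing_state_rate
  panel$state[skip] <- -2L
  panel$arthritis[skip] <- NA_integer_
  panel$obese[skip] <- NA_integer_
  panel$state[unk] <- -1L
  if (inherits(cohort, "hwle_cohort")) {
    cohort$panel <- panel
    cohort
  } else {
    panel
  }
}

# map coded states back to raw survey answers (fixture mode for panel prep)
cohort_to_answers <- function(cohort) {
  panel <- cohort$panel
  n <- nrow(panel)
  healthy <- panel$state %in% c(1, 2)
  working <- panel$state %in% c(1, 3)
  unknown <- panel$state == -1
  skipped <- panel$state == -2
  yn <- function(x) ifelse(x, "yes", "no")
  lim <- matrix("no", n, 3)
  nh <- which(!healthy & !unknown & !skipped)
  # a not-healthy respondent answers "yes" on a uniformly chosen number of
  # the three limitation items, then a uniformly chosen subset of that size
  patterns <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  ppat <- c(rep(1 / 9, 6), 1 / 3)
  if (length(nh)) {
    pi <- sample.int(7, length(nh), replace = TRUE, prob = ppat)
    lim[nh, ] <- ifelse(patterns[pi, , drop = FALSE] == 1, "yes", "no")
  }
  lim[unknown | skipped, ] <- NA_character_
  employment <- ifelse(working, "working now",
                       sample(c("retired", "unemployed and looking for work",
                                "disabled and unable to work", "a homemaker",
                                "temporarily laid off"), n, replace = TRUE))
  employment[unknown | skipped] <- NA_character_
  # heights fixed per person; weights consistent with obesity per wave
  ids <- unique(panel$id)
  height <- stats::setNames(round(stats::rnorm(length(ids), 1.70, 0.09), 2),
                            ids)
  height_m <- height[as.character(panel$id)]
  bmi <- ifelse(!is.na(panel$obese) & panel$obese == 1,
                stats::runif(n, 30, 40), stats::runif(n, 20, 29.5))
  body_weight <- round(bmi * height_m^2, 1)
  body_weight[skipped] <- NA_real_
  arth_ans <- yn(panel$arthritis == 1)
  arth_ans[skipped] <- NA_character_
  # occasional missing covariate answers among participated waves
  mcov <- !skipped & stats::runif(n) < 0.03
  arth_ans[mcov] <- NA_character_
  body_weight[!skipped & stats::runif(n) < 0.03] <- NA_real_
  state_pool <- split(us_state_regions()$state, us_state_regions()$region)
  us_state <- character(n)
  for (r in names(state_pool)) {
    idx <- panel$region == r
    us_state[idx] <- sample(state_pool[[r]], sum(idx), replace = TRUE)
  }
  educ_lab <- ifelse(panel$educ_hs == 1,
                     sample(c("high school diploma", "GED",
                              "college or higher"), n, replace = TRUE),
                     "less than high school")
  data.frame(
    id = panel$id,
    interview_date = panel$date,
    participated = !skipped,
    birth_date = panel$birth_date,
    death_date = panel$death_date,
    sex = ifelse(panel$sex_female == 1, "female", "male"),
    education = educ_lab,
    ethnicity = c(black = "Black or African American", white = "White",
                  other = "other")[panel$ethnicity],
    us_state = us_state,
    weight_cs = panel$weight,
    limit_paid_work = lim[, 1],
    limit_housework = lim[, 2],
    limit_activities = lim[, 3],
    employment = employment,
    arthritis_dx = arth_ans,
    height = unname(height_m),
    body_weight = body_weight,
    stringsAsFactors = FALSE
  )
}

#' Simulate full state trajectories and occupancy times under known parameters
#'
#' Monte-Carlo oracle for the expectancy calculations: simulates `n`
#' trajectories from the anchor age until death or the horizon and returns
#' per-state occupancy years (trapezoidal weighting of the step-grid
#' indicator, matching the expectancy integration rule).
#'
#' @param params,structure ground-truth model.
#' @param n number of trajectories.
#' @param age_anchor starting age.
#' @param init_probs length-4 initial state distribution (or a single state).
#' @param horizon years simulated.
#' @param covariates optional named covariate values (held fixed).
#' @return matrix `n x 4` of occupancy years by living state.
#' @export
simulate_occupancy <- function(params, structure, n, age_anchor = 50,
                               init_probs = c(1, 0, 0, 0), horizon = 60,
                               covariates = NULL) {
  h <- structure$step_months / 12
  K <- round(horizon / h)
  if (length(init_probs) == 1) {
    s <- rep(as.integer(init_probs), n)
  } else {
    s <- sample.int(4L, n, replace = TRUE, prob = init_probs)
  }
  covs <- list(arthritis = rep(0L, n), obese = rep(0L, n),
               sex_female = rep(0L, n), educ_hs = rep(0L, n))
  if (!is.null(covariates)) {
    for (nm in names(covariates)) covs[[nm]] <- rep(covariates[[nm]], n)
  }
  occ <- matrix(0, n, 4)
  ind <- function(states) {
    m <- matrix(0, length(states), 4)
    liv <- states <= 4
    m[cbind(which(liv), states[liv])] <- 1
    m
  }
  cur <- ind(s)
  for (k in seq_len(K)) {
    alive <- which(s <= 4L)
    snew <- s
    if (length(alive)) {
      age_k <- age_anchor + (k - 1) * h
      snew[alive] <- advance_states(
        s[alive], rep(age_k - structure$age_center, length(alive)),
        lapply(covs, function(v) v[alive]), params, structure, 1)
    }
    nxt <- ind(snew)
    occ <- occ + 0.5 * h * (cur + nxt)
    s <- snew
    cur <- nxt
  }
  occ
}
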
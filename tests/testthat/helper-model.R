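# Shared fixtures: small structures, toy panels, and the memoised replicate
# recovery study used by the heavier statistical checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

full_structure <- transition_structure()

# alive/dead toy: a single permitted transition 1 -> dead, no age effect
death_only_structure <- transition_structure(permitted = cbind(1, 5),
                                             include_age = FALSE)

# three-state chain within {1, 2, dead} (used for hand-computed sums)
chain_structure <- transition_structure(
  permitted = rbind(c(1, 2), c(1, 5), c(2, 1), c(2, 5)))

random_params <- function(structure, seed, sd = 0.6, intercept = -1.5) {
  set.seed(seed)
  init_params(structure, intercept = intercept) +
    stats::rnorm(structure$n_par, 0, sd)
}

# minimal coded panel from explicit per-person observation lists
make_panel <- function(persons) {
  rows <- lapply(seq_along(persons), function(i) {
    p <- persons[[i]]
    n <- length(p$state)
    data.frame(
      id = i,
      date = p$date,
      age = p$age,
      state = p$state,
      arthritis = p$arthritis %||% rep(0L, n),
      obese = p$obese %||% rep(0L, n),
      sex_female = 0L, educ_hs = 1L,
      ethnicity = "white", region = "South",
      weight = p$weight %||% 1,
      birth_date = "1944-06",
      death_date = p$death_date %||% "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# memoised 100-replicate parameter/HWLE recovery study (n = 2000, 14 waves)
recovery_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- transition_structure()
    truth <- default_true_params(s)
    w_true <- c(0.55, 0.20, 0.10, 0.15)
    true_hwle <- population_expectancies(
      conditional_state_expectancies(truth, structure = s), w_true)$HWLE
    R <- 100
    est <- matrix(NA_real_, R, s$n_par)
    cover <- matrix(NA, R, s$n_par)
    hwle_hat <- hwle_lo <- hwle_hi <- rep(NA_real_, R)
    conv <- logical(R)
    init <- NULL  # warm-start each replicate at the previous optimum: the
                  # maximiser is the same, only the iteration count drops
    for (r in seq_len(R)) {
      cfg <- true_model_config(n_individuals = 2000, seed = 5000 + r)
      panel <- generate_cohort(cfg)$panel
      fit <- suppressWarnings(fit_mle(panel, s, init = init))
      if (fit$convergence$converged) init <- coef(fit)
      conv[r] <- fit$convergence$converged && !is.null(fit$vcov)
      if (!conv[r]) next
      est[r, ] <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      cover[r, ] <- abs(coef(fit) - truth) <= 1.959964 * se
      prev <- initial_prevalence(panel, 50, 2)
      ci <- confidence_intervals(fit, prev, n_draws = 400, seed = 80000 + r)
      hwle_hat[r] <- ci$point$HWLE
      hwle_lo[r] <- ci$ci[1, "HWLE"]
      hwle_hi[r] <- ci$ci[2, "HWLE"]
    }
    cache <<- list(truth = truth, true_hwle = true_hwle, est = est,
                   cover = cover, hwle_hat = hwle_hat, hwle_lo = hwle_lo,
                   hwle_hi = hwle_hi, conv = conv, R = R)
    cache
  }
})
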
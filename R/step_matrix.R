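# Step transition matrices and interval probabilities.
#
# The estimator decomposes each observed multi-year interval into short
# interpolation steps (12 months by default). Within a step the transition
# probabilities from living state i follow a multinomial logit with the
# self-transition as reference:
#   p_ij = exp(eta_ij) / (1 + sum_k exp(eta_ik)),   p_ii = 1 / (1 + sum_k ...)
# and the dead row is the unit vector on dead. Interval probabilities are
# entries of the ordered product of step matrices, ages advancing per step.

#' One-step transition probability matrix
#'
#' @param age age in years at the start of the step.
#' @param params named parameter vector (layout of the structure).
#'   `-Inf` entries are allowed and act as structural zeros.
#' @param structure an [transition_structure()] object.
#' @param covariates named numeric vector of covariate values when the
#'   structure has covariates, else `NULL`.
#' @return a 5 x 5 row-stochastic matrix; rows/cols ordered 1,2,3,4,dead.
#' @export
#' @examples
#' s <- transition_structure(permitted = cbind(1, 2))
#' p <- init_params(s, intercept = 0, age_slope = 0)
#' step_transition_matrix(50, p, s)[1, 1:2]  # 0.5, 0.5
step_transition_matrix <- function(age, params, structure, covariates = NULL) {
  stopifnot(inherits(structure, "hwle_structure"))
  if (any(is.nan(params))) stop("NaN in parameter vector")
  if (any(params == Inf)) stop("+Inf in parameter vector")
  if (!is.finite(age) || age < 0) stop("age must be a non-negative number")
  eta <- linear_predictors(age, params, structure, covariates)
  P <- matrix(0, 5, 5)
  from <- structure$pairs[, "from"]
  to <- structure$pairs[, "to"]
  for (i in 1:4) {
    sel <- from == i
    if (!any(sel)) {
      P[i, i] <- 1
      next
    }
    e <- eta[sel]
    m <- max(0, e[is.finite(e)])        # log-sum-exp guard (self has eta = 0)
    w <- exp(e - m)
    w0 <- exp(-m)
    z <- w0 + sum(w)
    P[i, to[sel]] <- w / z
    P[i, i] <- w0 / z
  }
  P[5, 5] <- 1
  P
}

# interval decomposition: number of whole steps and trailing fraction
interval_steps <- function(age_a, age_b, step_months) {
  h <- step_months / 12
  s <- (age_b - age_a) / h
  if (s < -1e-9) stop("interval end precedes start")
  nfull <- floor(s + 1e-9)
  frac <- s - nfull
  if (frac < 1e-9) frac <- 0
  list(nfull = as.integer(nfull), frac = frac, h = h)
}

# fractional step: linear interpolation between identity and the full step
# matrix, so transition probability is proportional to the elapsed fraction
# and the interval likelihood is continuous in the observation dates.
fractional_step <- function(P, frac) {
  diag(5) * (1 - frac) + frac * P
}

# ordered product of step matrices over [age_a, age_b)
interval_matrix <- function(age_a, age_b, params, structure,
                            covariates = NULL) {
  d <- interval_steps(age_a, age_b, structure$step_months)
  M <- diag(5)
  if (d$nfull > 0) {
    for (k in seq_len(d$nfull) - 1L) {
      M <- M %*% step_transition_matrix(age_a + k * d$h, params, structure,
                                        covariates)
    }
  }
  if (d$frac > 0) {
    P <- step_transition_matrix(age_a + d$nfull * d$h, params, structure,
                                covariates)
    M <- M %*% fractional_step(P, d$frac)
  }
  M
}

#' Interval transition probability by matrix product
#'
#' Probability of being in `state_b` at age `age_b` given `state_a` at age
#' `age_a`, computed as an entry of the ordered product of step transition
#' matrices (ages advancing one step at a time). A destination of `-1`
#' (alive, state unknown) sums the probability over the four living states.
#'
#' @param state_a origin state (1..4).
#' @param age_a,age_b ages in years at the interval endpoints
#'   (`age_b >= age_a`); intervals that are not whole multiples of the step
#'   end with a fractional step interpolated linearly towards the identity.
#' @param state_b destination: 1..4, 5 (dead) or -1 (any living state).
#' @param params,structure,covariates as in [step_transition_matrix()].
#' @return a probability.
#' @export
interval_transition_probability <- function(state_a, age_a, state_b, age_b,
                                            params, structure,
                                            covariates = NULL) {
  stopifnot(state_a %in% 1:4, state_b %in% c(-1, 1:5))
  M <- interval_matrix(age_a, age_b, params, structure, covariates)
  if (state_b == -1) sum(M[state_a, 1:4]) else M[state_a, state_b]
}

#' Interval transition probability by exhaustive path enumeration
#'
#' Independent oracle for [interval_transition_probability()]: sums, over all
#' intermediate state sequences, the products of single-step transition
#' probabilities. Exponential in the number of steps, so restricted to whole
#' intervals of at most 6 steps.
#'
#' @inheritParams interval_transition_probability
#' @return a probability, exact up to floating point.
#' @export
brute_force_interval_probability <- function(state_a, age_a, state_b, age_b,
                                             params, structure,
                                             covariates = NULL) {
  stopifnot(state_a %in% 1:4, state_b %in% c(-1, 1:5))
  d <- interval_steps(age_a, age_b, structure$step_months)
  if (d$frac > 0) stop("path enumeration requires a whole number of steps")
  if (d$nfull > 6) stop("refusing path enumeration beyond 6 steps (5^steps paths)")
  if (d$nfull == 0) {
    return(as.numeric(if (state_b == -1) state_a %in% 1:4
                      else state_a == state_b))
  }
  mats <- lapply(seq_len(d$nfull) - 1L, function(k) {
    step_transition_matrix(age_a + k * d$h, params, structure, covariates)
  })
  target <- if (state_b == -1) 1:4 else state_b
  recur <- function(state, k) {
    if (k > d$nfull) return(as.numeric(state %in% target))
    tot <- 0
    for (nxt in 1:5) {
      p <- mats[[k]][state, nxt]
      if (p > 0) tot <- tot + p * recur(nxt, k + 1L)
    }
    tot
  }
  recur(state_a, 1L)
}
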
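# The five-state transition structure and its parameter layout.
#
# States: 1 = healthy & working, 2 = healthy & not working, 3 = not healthy &
# working, 4 = not healthy & not working, 5 = dead (absorbing). Each permitted
# transition (i, j), i != j, carries a multinomial logit
#   eta_ij = a_ij + b_ij * (age - age_center) + c_ij' x
# with the self-transition as the reference category of row i.

#' Define the permitted-transition structure of the five-state model
#'
#' The default structure permits all 12 ordered pairs among the four living
#' states plus the four living-to-dead transitions (16 modelled logits); no
#' transition leaves the dead state. A subset of pairs can be supplied to
#' build reduced models (used heavily by the closed-form test oracles).
#'
#' @param covariates character vector of binary covariate names entering every
#'   logit (e.g. `c("arthritis", "obese")`); empty for the age-only model.
#' @param permitted two-column matrix/data.frame of permitted `(from, to)`
#'   pairs with `from` in 1..4 and `to` in 1..5; `NULL` for the full set.
#' @param step_months length of one interpolation step in months (default 12).
#' @param age_center age (years) at which intercepts are anchored; age enters
#'   each logit as `age - age_center`. Default 50, the reference age of the
#'   expectancy calculations.
#' @param include_age logical; if `FALSE` the per-year age slope is dropped
#'   from every logit (time-homogeneous model, used by closed-form oracles).
#' @return an object of class `hwle_structure`: list with elements `pairs`
#'   (integer matrix), `covariates`, `step_months`, `age_center`,
#'   `include_age`, `n_living`, `dead`, `n_pairs`, `n_par`, `par_names`.
#' @export
#' @examples
#' s <- transition_structure()
#' s$n_par  # 16 logits x (intercept + age slope)
transition_structure <- function(covariates = character(0),
                                 permitted = NULL,
                                 step_months = 12,
                                 age_center = 50,
                                 include_age = TRUE) {
  if (is.null(permitted)) {
    permitted <- cbind(
      from = rep(1:4, each = 4),
      to = unlist(lapply(1:4, function(i) setdiff(1:5, i)))
    )
  }
  permitted <- as.matrix(permitted)
  storage.mode(permitted) <- "integer"
  colnames(permitted) <- c("from", "to")
  if (nrow(permitted) < 1) stop("at least one permitted transition required")
  if (any(permitted[, "from"] < 1 | permitted[, "from"] > 4)) {
    stop("'from' states must be living states 1..4")
  }
  if (any(permitted[, "to"] < 1 | permitted[, "to"] > 5)) {
    stop("'to' states must be in 1..5")
  }
  if (any(permitted[, "from"] == permitted[, "to"])) {
    stop("self-transitions are the reference category, not parameters")
  }
  if (anyDuplicated(paste(permitted[, 1], permitted[, 2]))) {
    stop("duplicated permitted pairs")
  }
  # keep pairs grouped by origin state (required by the C++ kernel)
  permitted <- permitted[order(permitted[, "from"], permitted[, "to"]), ,
                         drop = FALSE]
  covariates <- as.character(covariates)
  stopifnot(step_months > 0)
  npp <- 1L + as.integer(include_age) + length(covariates)
  lab <- function(s) ifelse(s == 5, "D", as.character(s))
  base <- sprintf("%d>%s", permitted[, "from"], lab(permitted[, "to"]))
  nm <- character(0)
  for (k in seq_len(nrow(permitted))) {
    nm <- c(nm, sprintf("a[%s]", base[k]),
            if (include_age) sprintf("b[%s]", base[k]),
            if (length(covariates)) sprintf("%s[%s]", covariates, base[k]))
  }
  structure(
    list(pairs = permitted, covariates = covariates,
         step_months = step_months, age_center = age_center,
         include_age = include_age, n_living = 4L, dead = 5L,
         n_pairs = nrow(permitted), n_par_per_pair = npp,
         n_par = nrow(permitted) * npp, par_names = nm),
    class = "hwle_structure"
  )
}

#' @export
print.hwle_structure <- function(x, ...) {
  cat("Five-state HWLE transition structure\n")
  cat(sprintf("  %d permitted transitions, %d parameters (%s%s)\n",
              x$n_pairs, x$n_par,
              if (x$include_age) "intercept + age slope" else "intercept",
              if (length(x$covariates)) {
                paste0(" + ", paste(x$covariates, collapse = ", "))
              } else ""))
  cat(sprintf("  step length %g months, age centred at %g years\n",
              x$step_months, x$age_center))
  invisible(x)
}

#' Build a parameter vector for a transition structure
#'
#' @param structure an `hwle_structure`.
#' @param intercept value for every intercept (default -4, the fitting
#'   default: all exits rare a priori).
#' @param age_slope value for every per-year age slope.
#' @param covariate value for every covariate coefficient.
#' @return named numeric vector of length `structure$n_par`.
#' @export
init_params <- function(structure, intercept = -4, age_slope = 0,
                        covariate = 0) {
  stopifnot(inherits(structure, "hwle_structure"))
  v <- numeric(0)
  for (k in seq_len(structure$n_pairs)) {
    v <- c(v, intercept,
           if (structure$include_age) age_slope,
           rep(covariate, length(structure$covariates)))
  }
  names(v) <- structure$par_names
  v
}

#' Set one transition's parameters inside a parameter vector
#'
#' Convenience accessor used when writing ground-truth configurations:
#' `set_par(p, s, 1, 5, a = -5.5, b = 0.09)` sets the intercept and age slope
#' of the 1 -> dead logit.
#'
#' @param params named parameter vector from [init_params()].
#' @param structure the matching `hwle_structure`.
#' @param from,to the transition.
#' @param a,b intercept and age slope (either may be `NULL` to leave as is).
#' @param ... named covariate coefficients, e.g. `arthritis = 0.5`.
#' @return the modified parameter vector.
#' @export
set_par <- function(params, structure, from, to, a = NULL, b = NULL, ...) {
  k <- which(structure$pairs[, "from"] == from & structure$pairs[, "to"] == to)
  if (length(k) != 1) stop("transition ", from, "->", to, " not permitted")
  off <- (k - 1L) * structure$n_par_per_pair
  if (!is.null(a)) params[off + 1L] <- a
  if (!is.null(b)) {
    if (!structure$include_age) stop("structure has no age slopes")
    params[off + 2L] <- b
  }
  dots <- list(...)
  for (nmc in names(dots)) {
    j <- match(nmc, structure$covariates)
    if (is.na(j)) stop("unknown covariate: ", nmc)
    params[off + 1L + as.integer(structure$include_age) + j] <- dots[[nmc]]
  }
  params
}

# internal: linear predictors for all pairs at one age/covariate setting
linear_predictors <- function(age, params, structure, covariates = NULL) {
  npp <- structure$n_par_per_pair
  idx <- (seq_len(structure$n_pairs) - 1L) * npp
  eta <- params[idx + 1L]
  if (structure$include_age) {
    eta <- eta + params[idx + 2L] * (age - structure$age_center)
  }
  ncov <- length(structure$covariates)
  if (ncov) {
    x <- covariate_vector(covariates, structure)
    base <- 1L + as.integer(structure$include_age)
    for (j in seq_len(ncov)) {
      eta <- eta + params[idx + base + j] * x[j]
    }
  }
  eta
}

covariate_vector <- function(covariates, structure) {
  ncov <- length(structure$covariates)
  if (ncov == 0L) return(numeric(0))
  if (is.null(covariates)) {
    stop("structure has covariates (", paste(structure$covariates,
         collapse = ", "), ") but none supplied")
  }
  if (is.null(names(covariates))) {
    if (length(covariates) != ncov) stop("covariate vector has wrong length")
    x <- as.numeric(covariates)
  } else {
    miss <- setdiff(structure$covariates, names(covariates))
    if (length(miss)) stop("missing covariate value(s): ",
                           paste(miss, collapse = ", "))
    x <- as.numeric(covariates[structure$covariates])
  }
  if (anyNA(x)) stop("NA covariate value")
  x
}
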
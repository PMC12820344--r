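# Interval-censored weighted likelihood over a coded panel.
#
# Each person's observation sequence is evaluated with a scaled forward
# algorithm: a row vector over the five states is propagated through step
# matrices and collapsed at each observation. Observed living states select
# one entry; "alive, state unknown" (-1) zeroes the dead entry and sums over
# living states; skipped waves (-2) contribute nothing and the interval
# chains across them; a known death date contributes the probability of
# surviving to the final step before death and dying within it. The person's
# longitudinal weight multiplies the total.

# required columns of a coded panel
panel_required_cols <- function(covariates = character(0)) {
  c("id", "date", "age", "state", "weight", "death_date", covariates)
}

check_panel <- function(panel, covariates = character(0)) {
  miss <- setdiff(panel_required_cols(covariates), names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !panel$state %in% c(-2, -1, 1:4)
  if (any(bad)) {
    stop("invalid state code(s) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  invisible(panel)
}

# Build the flat operation stream consumed by the C++ kernel.
build_likelihood_data <- function(panel, structure) {
  covs <- structure$covariates
  check_panel(panel, covs)
  panel <- panel[panel$state != -2, , drop = FALSE]
  ord <- order(panel$id, ym_parse(panel$date))
  panel <- panel[ord, , drop = FALSE]
  ncov <- length(covs)
  if (ncov) {
    V <- as.matrix(panel[covs])
    storage.mode(V) <- "double"
    if (anyNA(V)) stop("NA covariate values in panel (run panel prep first)")
    key <- apply(V, 1, paste, collapse = "\r")
    ukey <- unique(key)
    xidx_row <- match(key, ukey)
    X <- t(V[match(ukey, key), , drop = FALSE])
  } else {
    X <- matrix(0, nrow = 0, ncol = 1)
    xidx_row <- rep(1L, nrow(panel))
  }
  h <- structure$step_months / 12
  ctr <- structure$age_center

  ids <- unique(panel$id)
  dates_m <- ym_parse(panel$date)
  death_m_all <- suppressWarnings(ym_parse(ifelse(is.na(panel$death_date), "",
                                                  panel$death_date)))

  acc_type <- list(); acc_arg <- list()
  acc_t <- list(); acc_frac <- list(); acc_x <- list()
  p_nops <- integer(0); p_init <- integer(0); w <- numeric(0)
  idx_by_id <- split(seq_len(nrow(panel)), factor(panel$id, levels = ids))
  for (rows in idx_by_id) {
    st <- panel$state[rows]
    first <- which(st %in% 1:4)[1]
    if (is.na(first)) next  # no known living state: non-informative
    rows <- rows[first:length(rows)]
    st <- st[first:length(st)]
    otype <- integer(0); oarg <- integer(0)
    ot <- numeric(0); ofrac <- numeric(0); ox <- integer(0)
    emit_steps <- function(t0, xo, nfull, frac, final_type) {
      # steps within one interval; final_type 3 marks the death step
      if (nfull > 0) {
        ot <<- c(ot, t0 + (seq_len(nfull) - 1) * h)
        ofrac <<- c(ofrac, rep(1, nfull))
        ox <<- c(ox, rep(xo, nfull))
        otype <<- c(otype, rep(0L, nfull))
        oarg <<- c(oarg, rep(-1L, nfull))
      }
      if (frac > 0) {
        ot <<- c(ot, t0 + nfull * h)
        ofrac <<- c(ofrac, frac)
        ox <<- c(ox, xo)
        otype <<- c(otype, if (final_type == 3L) 3L else 0L)
        oarg <<- c(oarg, -1L)
      } else if (final_type == 3L) {
        # death at a whole number of steps: the last full step is the death
        # step, so retype it
        otype[length(otype)] <<- 3L
      }
    }
    origin <- rows[1]
    for (k in seq_along(rows)[-1]) {
      dm <- dates_m[rows[k]] - dates_m[origin]
      if (dm <= 0) stop("non-increasing interview dates for id ",
                        panel$id[origin])
      s <- dm / structure$step_months
      nfull <- floor(s + 1e-9)
      frac <- s - nfull
      if (frac < 1e-9) frac <- 0
      emit_steps(panel$age[origin] - ctr, xidx_row[origin] - 1L, nfull, frac,
                 0L)
      if (st[k] == -1) {
        otype <- c(otype, 2L); oarg <- c(oarg, 0L)
      } else {
        otype <- c(otype, 1L); oarg <- c(oarg, st[k] - 1L)
      }
      origin <- rows[k]
    }
    dmth <- death_m_all[rows[length(rows)]]
    if (!is.na(dmth)) {
      dm <- dmth - dates_m[origin]
      if (dm <= 0) {
        stop("death date not after last interview for id ", panel$id[origin])
      }
      s <- dm / structure$step_months
      nfull <- ceiling(s - 1e-9) - 1L
      frac <- s - nfull
      emit_steps(panel$age[origin] - ctr, xidx_row[origin] - 1L, nfull, frac,
                 3L)
    }
    acc_type[[length(acc_type) + 1L]] <- otype
    acc_arg[[length(acc_arg) + 1L]] <- oarg
    acc_t[[length(acc_t) + 1L]] <- ot
    acc_frac[[length(acc_frac) + 1L]] <- ofrac
    acc_x[[length(acc_x) + 1L]] <- ox
    p_nops <- c(p_nops, length(otype))
    p_init <- c(p_init, st[1] - 1L)
    wgt <- panel$weight[rows[1]]
    if (is.na(wgt) || wgt < 0) stop("missing/negative weight for id ",
                                    panel$id[rows[1]])
    w <- c(w, wgt)
  }
  op_type <- unlist(acc_type) %||% integer(0)
  op_arg <- unlist(acc_arg) %||% integer(0)
  step_t <- unlist(acc_t) %||% numeric(0)
  step_frac <- unlist(acc_frac) %||% numeric(0)
  step_x <- unlist(acc_x) %||% integer(0)
  p_start <- cumsum(c(0L, p_nops))[seq_along(p_nops)]
  is_step <- op_type == 0L | op_type == 3L
  op_arg[is_step] <- seq_len(sum(is_step)) - 1L
  # deduplicate steps: matrices depend only on (age, fraction, covariates),
  # and interview dates sit on a month grid, so few combinations are distinct
  if (length(step_t)) {
    key <- paste(sprintf("%.9f", step_t), sprintf("%.9f", step_frac), step_x)
    ukey <- unique(key)
    remap <- match(key, ukey)
    keep <- match(ukey, key)
    is_step <- op_type == 0L | op_type == 3L
    op_arg[is_step] <- remap[op_arg[is_step] + 1L] - 1L
    step_t <- step_t[keep]
    step_frac <- step_frac[keep]
    step_x <- step_x[keep]
  }
  base::structure(
    list(pair_from = as.integer(structure$pairs[, "from"] - 1L),
         pair_to = as.integer(structure$pairs[, "to"] - 1L),
         npp = structure$n_par_per_pair,
         ncov = ncov, has_age = as.integer(structure$include_age),
         X = X,
         step_t = step_t, step_frac = step_frac, step_x = step_x,
         op_type = op_type, op_arg = op_arg,
         p_start = p_start, p_nops = p_nops, p_init = p_init, w = w,
         n_persons = length(p_start)),
    class = "hwle_likdata"
  )
}

#' Weighted log-likelihood contribution of one person
#'
#' Pure-R reference implementation of the per-person likelihood (the fitting
#' path uses a compiled equivalent; the two are tested against each other).
#' Observations must be time-ordered rows of a coded panel for a single
#' person. A lone observation with no follow-up contributes 0.
#'
#' @param obs data.frame with the coded-panel columns for one person.
#' @param params,structure model parameters and structure.
#' @return the person's weight times their log-likelihood.
#' @export
individual_log_likelihood <- function(obs, params, structure) {
  covs <- structure$covariates
  check_panel(obs, covs)
  if (length(unique(obs$id)) > 1) stop("observations from more than one person")
  obs <- obs[obs$state != -2, , drop = FALSE]
  obs <- obs[order(ym_parse(obs$date)), , drop = FALSE]
  first <- which(obs$state %in% 1:4)[1]
  if (is.na(first)) return(0)
  obs <- obs[first:nrow(obs), , drop = FALSE]
  alpha <- numeric(5)
  alpha[obs$state[1]] <- 1
  logl <- 0
  dm <- ym_parse(obs$date)
  getx <- function(i) {
    if (length(covs)) unlist(obs[i, covs]) else NULL
  }
  origin <- 1L
  for (k in seq_len(nrow(obs))[-1]) {
    age_a <- obs$age[origin]
    age_b <- age_a + (dm[k] - dm[origin]) / 12
    M <- interval_matrix(age_a, age_b, params, structure, getx(origin))
    alpha <- alpha %*% M
    if (obs$state[k] == -1) {
      alpha[5] <- 0
      cst <- sum(alpha)
      if (cst <= 0) return(-Inf * obs$weight[1])
      logl <- logl + log(cst)
      alpha <- alpha / cst
    } else {
      cst <- alpha[obs$state[k]]
      if (cst <= 0) return(-Inf * obs$weight[1])
      logl <- logl + log(cst)
      alpha <- numeric(5)
      alpha[obs$state[k]] <- 1
    }
    origin <- k
  }
  ddate <- obs$death_date[nrow(obs)]
  if (!is.na(ddate) && nzchar(ddate)) {
    dmo <- ym_parse(ddate) - dm[origin]
    if (dmo <= 0) stop("death date not after last interview")
    s <- dmo / structure$step_months
    nfull <- ceiling(s - 1e-9) - 1
    frac <- s - nfull
    h <- structure$step_months / 12
    age_a <- obs$age[origin]
    M <- interval_matrix(age_a, age_a + nfull * h, params, structure,
                         getx(origin))
    alpha <- alpha %*% M
    Pd <- step_transition_matrix(age_a + nfull * h, params, structure,
                                 getx(origin))
    cst <- sum(alpha[1:4] * frac * Pd[1:4, 5])
    if (cst <= 0) return(-Inf * obs$weight[1])
    logl <- logl + log(cst)
  }
  obs$weight[1] * logl
}

#' Total weighted log-likelihood of a coded panel
#'
#' @param panel coded panel data.frame (see [read_panel()] for the dialect).
#' @param params named parameter vector.
#' @param structure the model [transition_structure()].
#' @param likdata optional prebuilt likelihood data (internal reuse).
#' @return scalar log-likelihood (sum of weighted person contributions).
#' @export
total_log_likelihood <- function(panel, params, structure, likdata = NULL) {
  if (is.null(likdata)) likdata <- build_likelihood_data(panel, structure)
  -negloglik_cpp(as.numeric(params), unclass(likdata))
}
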
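# Maximum-likelihood fitting of the step-transition model.

#' Fit the interpolated Markov chain transition model by maximum likelihood
#'
#' Maximises the weighted interval-censored log-likelihood with BFGS using an
#' analytic gradient. The covariance of the estimates is the inverse of the
#' observed information, obtained by numerically differentiating the analytic
#' gradient at the optimum.
#'
#' @param panel coded panel data.frame (columns `id`, `date`, `age`, `state`,
#'   `weight`, `death_date`, plus any covariate columns named in `structure`).
#' @param structure the model [transition_structure()]; its `covariates`
#'   determine which panel columns enter the logits.
#' @param init optional initial parameter vector; default intercepts -4,
#'   slopes and covariate coefficients 0.
#' @param control list of options: `maxit` (default 500), `reltol`
#'   (default 1e-9: the optimiser stops when the relative log-likelihood
#'   change falls below it), `grad_tol`
#'   (default 1e-5, max-norm declaring gradient convergence), `hessian_step`
#'   (default 1e-5, relative step of the information matrix differencing).
#' @param compute_vcov logical; skip the information matrix when `FALSE`
#'   (used inside replicate studies that only need point estimates).
#' @return an object of class `hwle_fit`: list with `coefficients`, `vcov`
#'   (`NULL` if unavailable), `logLik`, `convergence` (list with `converged`,
#'   `optim_code`, `gradient_max`, `iterations`), `structure`, `n_persons`.
#'   Non-convergence is reported in `convergence` and as a warning, never
#'   silently.
#' @export
fit_mle <- function(panel, structure = transition_structure(), init = NULL,
                    control = list(), compute_vcov = TRUE) {
  stopifnot(inherits(structure, "hwle_structure"))
  ctl <- list(maxit = 500L, reltol = 1e-9, grad_tol = 1e-5,
              hessian_step = 1e-5)
  ctl[names(control)] <- control
  likdata <- build_likelihood_data(panel, structure)
  if (likdata$n_persons == 0) stop("no informative persons in panel")
  pk <- unclass(likdata)
  if (is.null(init)) init <- init_params(structure)
  if (length(init) != structure$n_par) stop("init has wrong length")
  if (any(!is.finite(init))) stop("init must be finite")
  fn <- function(p) negloglik_cpp(p, pk)
  gr <- function(p) negloglik_grad_cpp(p, pk)$gradient
  opt <- stats::optim(as.numeric(init), fn, gr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  est <- opt$par
  names(est) <- structure$par_names
  g <- gr(est)
  gmax <- max(abs(g))
  converged <- (opt$convergence == 0) || (gmax < ctl$grad_tol)
  if (!converged) {
    warning(sprintf(
      "fit did not converge (optim code %d, max |gradient| %.3g)",
      opt$convergence, gmax))
  }
  vcov <- NULL
  vcov_msg <- NULL
  if (compute_vcov) {
    H <- observed_information(gr, est, ctl$hessian_step)
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov) && all(is.finite(vcov))) {
      ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE)
      if (min(ev$values) > -1e-6 * max(abs(ev$values))) {
        # clamp numerically negative eigenvalues from the differencing noise
        vals <- pmax(ev$values, 0)
        vcov <- ev$vectors %*% (vals * t(ev$vectors))
      } else {
        vcov <- NULL
      }
    } else {
      vcov <- NULL
    }
    if (is.null(vcov) || any(diag(vcov) <= 0)) {
      vcov <- NULL
      vcov_msg <- "observed information singular or not positive definite"
    } else {
      dimnames(vcov) <- list(structure$par_names, structure$par_names)
    }
  }
  base::structure(
    list(coefficients = est, vcov = vcov, vcov_message = vcov_msg,
         logLik = -opt$value,
         convergence = list(converged = converged,
                            optim_code = opt$convergence,
                            gradient_max = gmax,
                            iterations = opt$counts[["function"]]),
         structure = structure, n_persons = likdata$n_persons,
         likdata = likdata),
    class = "hwle_fit"
  )
}

# forward-difference Hessian of the negative log-likelihood from its
# analytic gradient, symmetrised
observed_information <- function(gr, theta, rel_step = 1e-5) {
  p <- length(theta)
  g0 <- gr(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    d <- rel_step * (1 + abs(theta[j]))
    th <- theta
    th[j] <- th[j] + d
    H[, j] <- (gr(th) - g0) / d
  }
  (H + t(H)) / 2
}

#' @export
print.hwle_fit <- function(x, ...) {
  cat("Interpolated Markov chain transition model fit\n")
  cat(sprintf("  %d persons, %d parameters, log-likelihood %.3f\n",
              x$n_persons, length(x$coefficients), x$logLik))
  cat(sprintf("  converged: %s (max |gradient| %.3g)\n",
              x$convergence$converged, x$convergence$gradient_max))
  if (is.null(x$vcov)) cat("  covariance unavailable:",
                           x$vcov_message %||% "not computed", "\n")
  invisible(x)
}

#' @export
coef.hwle_fit <- function(object, ...) object$coefficients

#' @export
vcov.hwle_fit <- function(object, ...) object$vcov

#' @export
logLik.hwle_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            class = "logLik")
}

#' Serialise a fitted model to a JSON file
#'
#' Writes the transition structure, parameter ordering, estimates, covariance
#' and convergence diagnostics to a plain-text JSON file; [read_model()]
#' restores an equivalent `hwle_fit` object (without the likelihood data).
#'
#' @param fit an `hwle_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "hwle_fit"))
  s <- fit$structure
  obj <- list(
    structure = list(pairs = unname(s$pairs), covariates = s$covariates,
                     step_months = s$step_months, age_center = s$age_center,
                     include_age = s$include_age),
    par_names = s$par_names,
    coefficients = unname(fit$coefficients),
    vcov = if (is.null(fit$vcov)) NULL else unname(fit$vcov),
    logLik = fit$logLik,
    convergence = fit$convergence,
    n_persons = fit$n_persons
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#' @param path JSON file path.
#' @return an `hwle_fit` object (without likelihood data).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- transition_structure(
    covariates = obj$structure$covariates %||% character(0),
    permitted = matrix(as.integer(obj$structure$pairs), ncol = 2),
    step_months = obj$structure$step_months,
    age_center = obj$structure$age_center,
    include_age = obj$structure$include_age
  )
  est <- as.numeric(obj$coefficients)
  names(est) <- s$par_names
  vc <- obj$vcov
  if (!is.null(vc)) {
    vc <- matrix(as.numeric(vc), nrow = length(est))
    dimnames(vc) <- list(s$par_names, s$par_names)
  }
  structure(
    list(coefficients = est, vcov = vc, vcov_message = NULL,
         logLik = obj$logLik, convergence = obj$convergence,
         structure = s, n_persons = obj$n_persons, likdata = NULL),
    class = "hwle_fit"
  )
}
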
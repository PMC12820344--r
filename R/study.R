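# Study orchestration: stratified estimates, descriptive tables and the
# calendar-period sensitivity analysis.

#' Default stratification plan
#'
#' Overall; by arthritis; and sex, education, region, ethnicity (Black or
#' African American and White only) and obesity each crossed with arthritis.
#'
#' @return list of character vectors of stratifying variables.
#' @export
default_strata <- function() {
  list(character(0), "arthritis",
       c("sex_female", "arthritis"), c("educ_hs", "arthritis"),
       c("region", "arthritis"), c("ethnicity", "arthritis"),
       c("obese", "arthritis"))
}

# Split a panel on a time-varying binary variable: each person's observation
# series is cut into maximal runs of constant value; runs become
# pseudo-persons (id suffixed), a death date stays with the final run, and
# every transition is used exactly once, classified by its origin value.
split_timevarying <- function(panel, var) {
  pieces <- list()
  for (d in split(panel, factor(panel$id, levels = unique(panel$id)))) {
    d <- d[order(ym_parse(d$date)), , drop = FALSE]
    v <- d[[var]]
    known <- !is.na(v)
    if (!any(known)) next
    d <- d[known, , drop = FALSE]
    v <- v[known]
    run <- cumsum(c(1L, as.integer(v[-1] != v[-length(v)])))
    lastrun <- run[length(run)]
    for (r in unique(run)) {
      dd <- d[run == r, , drop = FALSE]
      if (r != lastrun) dd$death_date <- ""
      dd$id <- paste0(dd$id, ".", var, r)
      pieces[[length(pieces) + 1L]] <- dd
    }
  }
  if (!length(pieces)) return(panel[0, , drop = FALSE])
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# subset/split a panel to one stratum level
stratum_panel <- function(panel, vars, levels) {
  timevarying <- c("arthritis", "obese")
  d <- panel
  for (k in seq_along(vars)) {
    v <- vars[k]
    lev <- levels[[k]]
    if (v %in% timevarying) {
      d <- split_timevarying(d, v)
      d <- d[d[[v]] == lev, , drop = FALSE]
    } else {
      d <- d[!is.na(d[[v]]) & d[[v]] == lev, , drop = FALSE]
    }
  }
  d
}

stratum_levels <- function(panel, v) {
  if (v == "ethnicity") {
    intersect(c("black", "white", "Black or African American", "White"),
              unique(panel$ethnicity))
  } else {
    sort(unique(panel[[v]][!is.na(panel[[v]])]))
  }
}

#' Run the stratified HWLE analysis
#'
#' For each stratum: refits the transition model on the stratum's panel,
#' computes prevalence-weighted expectancies with simulation confidence
#' intervals, and reports HWLE, LE and HWLE as a percentage of LE. Strata
#' that are empty, fail to converge, or have too few observations to
#' identify the parameters are skipped with a logged diagnostic.
#'
#' @param panel prepped coded panel.
#' @param strata list of character vectors of stratifying variables (default
#'   [default_strata()]). Time-varying variables (arthritis, obesity) split
#'   each person's series into runs of constant value.
#' @param structure model structure used for every refit (stratified mode:
#'   no covariates in the logits). For pooled mode pass a structure with
#'   covariates and use [fit_mle()] directly.
#' @param age_anchor,window,horizon expectancy settings.
#' @param n_draws,seed confidence-interval simulation settings.
#' @param min_persons strata with fewer informative persons are skipped.
#' @return list of class `hwle_study`: `table` (one row per stratum level
#'   combination with HWLE/LE estimates, CIs and %HWLE of LE),
#'   `descriptives` (the [descriptive_table()]), `log` (character vector of
#'   per-stratum diagnostics).
#' @export
run_stratified_analysis <- function(panel, strata = default_strata(),
                                    structure = transition_structure(),
                                    age_anchor = 50, window = 2,
                                    horizon = 60, n_draws = 500,
                                    seed = NULL, min_persons = 50) {
  check_panel(panel)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  log <- character(0)
  for (vars in strata) {
    levsets <- if (!length(vars)) list(list()) else {
      grids <- lapply(vars, function(v) stratum_levels(panel, v))
      do.call(function(...) {
        g <- expand.grid(..., stringsAsFactors = FALSE)
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
      }, grids)
    }
    for (lev in levsets) {
      label <- if (!length(vars)) "overall" else {
        paste(paste0(vars, "=", unlist(lev)), collapse = ",")
      }
      d <- stratum_panel(panel, vars, lev)
      ninf <- length(unique(d$id[d$state %in% 1:4]))
      if (ninf < min_persons) {
        log <- c(log, sprintf("%s: skipped (%d informative persons)",
                              label, ninf))
        next
      }
      res <- tryCatch({
        fit <- fit_mle(d, structure)
        prev <- initial_prevalence(d, age_anchor, window)
        ci <- confidence_intervals(fit, prev, n_draws = n_draws,
                                   age_anchor = age_anchor,
                                   horizon = horizon)
        list(fit = fit, prev = prev, ci = ci)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log <- c(log, sprintf("%s: skipped (%s)", label,
                              conditionMessage(res)))
        next
      }
      log <- c(log, sprintf(
        "%s: %d persons, converged=%s, logLik=%.2f", label, ninf,
        res$fit$convergence$converged, res$fit$logLik))
      pt <- res$ci$point
      cim <- res$ci$ci
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = label, n_persons = ninf,
        hwle = pt$HWLE,
        hwle_lo = if (res$ci$available) cim[1, "HWLE"] else NA_real_,
        hwle_hi = if (res$ci$available) cim[2, "HWLE"] else NA_real_,
        hwle_se = if (res$ci$available) res$ci$se[["HWLE"]] else NA_real_,
        e1 = pt$E[[1]], e2 = pt$E[[2]], e3 = pt$E[[3]], e4 = pt$E[[4]],
        le = pt$LE,
        le_lo = if (res$ci$available) cim[1, "LE"] else NA_real_,
        le_hi = if (res$ci$available) cim[2, "LE"] else NA_real_,
        pct_hwle_of_le = percent_of_le(pt$HWLE, pt$LE),
        converged = res$fit$convergence$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  base::structure(list(table = table, descriptives = descriptive_table(panel),
                       log = log),
                  class = "hwle_study")
}

#' @export
print.hwle_study <- function(x, ...) {
  cat("Stratified HWLE analysis\n")
  if (is.null(x$table)) {
    cat("  (no estimable strata)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-40s HWLE %5.2f (%.2f-%.2f)  LE %5.2f  %%HWLE %d\n",
                r$stratum, r$hwle, r$hwle_lo, r$hwle_hi, r$le,
                r$pct_hwle_of_le))
  }
  invisible(x)
}

#' Observed and weighted descriptive counts
#'
#' Person-level table of counts and percentages (unweighted and survey
#' weighted) for sex, education, region, ethnicity, ever-reported arthritis
#' and ever-obese, mirroring a baseline characteristics table.
#'
#' @param panel coded panel.
#' @return data.frame with columns `variable`, `level`, `n`, `pct`,
#'   `weighted_n`, `weighted_pct`.
#' @export
descriptive_table <- function(panel) {
  check_panel(panel)
  by_id <- split(panel, factor(panel$id, levels = unique(panel$id)))
  pers <- do.call(rbind, lapply(by_id, function(d) {
    data.frame(
      sex = if (is.na(d$sex_female[1])) NA_character_ else {
        c("male", "female")[d$sex_female[1] + 1]
      },
      education = if (is.na(d$educ_hs[1])) NA_character_ else {
        c("less than high school", "high school education")[d$educ_hs[1] + 1]
      },
      region = d$region[1],
      ethnicity = d$ethnicity[1],
      arthritis_ever = if (all(is.na(d$arthritis))) NA_character_ else {
        c("no", "yes")[max(d$arthritis, na.rm = TRUE) + 1]
      },
      obese_ever = if (all(is.na(d$obese))) NA_character_ else {
        c("no", "yes")[max(d$obese, na.rm = TRUE) + 1]
      },
      weight = d$weight[1],
      stringsAsFactors = FALSE
    )
  }))
  rows <- list()
  for (v in c("sex", "education", "region", "ethnicity", "arthritis_ever",
              "obese_ever")) {
    x <- pers[[v]]
    ok <- !is.na(x)
    for (lev in sort(unique(x[ok]))) {
      sel <- ok & x == lev
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev,
        n = sum(sel),
        pct = round_half_away(100 * sum(sel) / sum(ok), 1),
        weighted_n = sum(pers$weight[sel]),
        weighted_pct = round_half_away(
          100 * sum(pers$weight[sel]) / sum(pers$weight[ok]), 1),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calendar-period sensitivity of state prevalence
#'
#' For each survey year and target age, the survey-weighted prevalence of
#' the four living states among respondents within `age_window` years of the
#' target age. The range of each prevalence across calendar years is
#' compared with a tolerance band: a range beyond the band flags a calendar
#' trend (an automated stand-in for visual trend assessment).
#'
#' @param panel coded panel.
#' @param ages target ages (default 55, 60, 65).
#' @param age_window half-width in years of the age window (default 1).
#' @param band tolerance band in percentage points (default 10).
#' @param min_n cells with fewer usable respondents are reported as missing
#'   (default 25); a handful of respondents cannot support a prevalence.
#' @return list of class `hwle_sensitivity`: `prevalence` (long data.frame:
#'   `year`, `age`, `state`, `prevalence`, `n`), `ranges` (per age/state
#'   range across years with `flag` = "stable"/"trend"), `flag` (overall).
#' @export
sensitivity_prevalence_by_wave <- function(panel, ages = c(55, 60, 65),
                                           age_window = 1, band = 10,
                                           min_n = 25) {
  check_panel(panel)
  yrs <- sort(unique(ym_year(ym_parse(panel$date))))
  yrs <- yrs[!is.na(yrs)]
  panel_year <- ym_year(ym_parse(panel$date))
  rows <- list()
  for (yr in yrs) {
    for (a in ages) {
      sel <- !is.na(panel_year) & panel_year == yr & panel$state %in% 1:4 &
        !is.na(panel$age) & abs(panel$age - a) <= age_window
      if (sum(sel) < min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, age = a, state = 1:4, prevalence = NA_real_,
          n = sum(sel))
        next
      }
      tot <- sum(panel$weight[sel])
      for (s in 1:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, age = a, state = s,
          prevalence = 100 * sum(panel$weight[sel & panel$state == s]) / tot,
          n = sum(sel))
      }
    }
  }
  prev <- do.call(rbind, rows)
  ranges <- NULL
  if (length(yrs) > 1) {
    ranges <- do.call(rbind, lapply(split(
      prev[!is.na(prev$prevalence), ],
      list(prev$age[!is.na(prev$prevalence)],
           prev$state[!is.na(prev$prevalence)])), function(d) {
        if (!nrow(d)) return(NULL)
        rng <- diff(range(d$prevalence))
        data.frame(age = d$age[1], state = d$state[1], range = rng,
                   flag = if (rng > band) "trend" else "stable",
                   stringsAsFactors = FALSE)
      }))
    rownames(ranges) <- NULL
  }
  structure(list(prevalence = prev, ranges = ranges,
                 flag = if (is.null(ranges)) NA_character_ else {
                   if (any(ranges$flag == "trend")) "trend" else "stable"
                 }),
            class = "hwle_sensitivity")
}
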
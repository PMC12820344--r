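# Survey coding, imputation, weighting and exclusion rules that turn raw
# panel answers into the analysis-ready coded panel.
#
# State codes: 1 healthy & working, 2 healthy & not working, 3 not healthy &
# working, 4 not healthy & not working; -1 alive with unknown state; -2
# unknown vital and health/work status (wave not participated). Death is not
# a state row: it is carried as a month-resolution death date per person.

#' Classify health from the three activity-limitation questions
#'
#' Healthy means no limitation reported on any of: limitation in kind/amount
#' of paid work, limitation in work around the house, limitation in any
#' activities. A single "yes" makes the respondent not healthy; the record is
#' missing only when none of the three questions was answered.
#'
#' @param a1,a2,a3 character vectors with values `"yes"`, `"no"` or `NA`
#'   (vectorised).
#' @return character vector: `"healthy"`, `"not_healthy"` or `"missing"`.
#' @export
classify_health <- function(a1, a2, a3) {
  chk <- function(x) {
    bad <- !is.na(x) & !x %in% c("yes", "no")
    if (any(bad)) stop("limitation answers must be yes/no/NA; got: ",
                       paste(unique(x[bad]), collapse = ", "))
    x
  }
  m <- cbind(chk(a1), chk(a2), chk(a3))
  any_yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  out <- rep("missing", nrow(m))
  out[any_yes] <- "not_healthy"
  out[!any_yes & !all_na] <- "healthy"  # missing only when no question answered
  out
}

employment_categories <- c(
  "working now", "temporarily laid off",
  "unemployed and looking for work", "disabled and unable to work",
  "retired", "a homemaker", "other"
)

#' Classify work status from the current-employment item
#'
#' Working means the answer "working now"; every other stated category is not
#' working; `NA` is missing.
#'
#' @param answer character vector of employment answers.
#' @return character vector: `"working"`, `"not_working"` or `"missing"`.
#' @export
classify_work <- function(answer) {
  bad <- !is.na(answer) & !answer %in% employment_categories
  if (any(bad)) {
    stop("unrecognised employment category: ",
         paste(unique(answer[bad]), collapse = ", "),
         "; allowed: ", paste(employment_categories, collapse = ", "))
  }
  out <- rep("missing", length(answer))
  out[!is.na(answer) & answer == "working now"] <- "working"
  out[!is.na(answer) & answer != "working now"] <- "not_working"
  out
}

#' Encode the five-state code from health, work and vital status
#'
#' @param health `"healthy"`, `"not_healthy"` or `"missing"` (vectorised).
#' @param work `"working"`, `"not_working"` or `"missing"`.
#' @param vital `"alive"`, `"dead"` or `"unknown"`.
#' @return integer state codes: 1..4, 5 (dead), -1 (alive, state unknown),
#'   -2 (unknown vital and health/work status).
#' @export
encode_state <- function(health, work, vital = "alive") {
  n <- max(length(health), length(work), length(vital))
  health <- rep_len(health, n)
  work <- rep_len(work, n)
  vital <- rep_len(vital, n)
  out <- integer(n)
  out[vital == "unknown"] <- -2L
  out[vital == "dead"] <- 5L
  alive <- vital == "alive"
  hmiss <- health == "missing" | work == "missing"
  out[alive & hmiss] <- -1L
  grid <- c("healthy.working" = 1L, "healthy.not_working" = 2L,
            "not_healthy.working" = 3L, "not_healthy.not_working" = 4L)
  key <- paste(health, work, sep = ".")
  ok <- alive & !hmiss
  out[ok] <- grid[key[ok]]
  out
}

#' Enforce irreversibility of arthritis across waves
#'
#' Arthritis is an ever-diagnosis: once reported it is carried forward to all
#' later waves (a later "no" is overridden), and it is taken as absent at and
#' before an explicit negative response unless an earlier "yes" exists.
#' Missing answers are first filled from the nearest observed wave
#' ([impute_time_varying_nearest()]), then the monotone rule is applied.
#'
#' @param answers character vector per wave: `"yes"`, `"no"` or `NA`.
#' @return integer 0/1 vector, monotone non-decreasing.
#' @export
enforce_arthritis_irreversibility <- function(answers) {
  bad <- !is.na(answers) & !answers %in% c("yes", "no")
  if (any(bad)) stop("arthritis answers must be yes/no/NA")
  v <- ifelse(is.na(answers), NA_integer_, as.integer(answers == "yes"))
  v <- impute_time_varying_nearest(v)
  as.integer(cummax(v))
}

#' Obesity from self-reported height and weight
#'
#' BMI is weight / height^2 in kg/m^2 (or 703 x lb/in^2 for US units);
#' obesity is BMI of 30 or higher (inclusive). Implausible heights (outside
#' 1.2-2.3 m or the US-unit equivalent) or non-positive inputs are treated as
#' missing with a warning.
#'
#' @param height height in metres (or inches for `unit_system = "us"`),
#'   vectorised.
#' @param weight body weight in kg (or pounds).
#' @param unit_system `"metric"` or `"us"`.
#' @return integer 0/1/NA obesity indicator.
#' @export
compute_bmi_obesity <- function(height, weight, unit_system = c("metric", "us")) {
  unit_system <- match.arg(unit_system)
  h_m <- if (unit_system == "us") height * 0.0254 else height
  bad <- (!is.na(height) & (height <= 0 | h_m < 1.2 | h_m > 2.3)) |
    (!is.na(weight) & weight <= 0)
  if (any(bad)) {
    warning(sum(bad), " record(s) with implausible height/weight treated as missing")
  }
  bmi <- if (unit_system == "us") 703 * weight / height^2 else {
    weight / height^2
  }
  bmi[bad] <- NA_real_
  ifelse(is.na(bmi), NA_integer_, as.integer(bmi >= 30))
}

#' US Census Bureau region of each state
#' @return data.frame with columns `state`, `region`.
#' @export
us_state_regions <- function() {
  midwest <- c("Illinois", "Indiana", "Iowa", "Kansas", "Michigan",
               "Minnesota", "Missouri", "Nebraska", "North Dakota", "Ohio",
               "South Dakota", "Wisconsin")
  northeast <- c("Connecticut", "Maine", "Massachusetts", "New Hampshire",
                 "New Jersey", "New York", "Pennsylvania", "Rhode Island",
                 "Vermont")
  south <- c("Alabama", "Arkansas", "Delaware", "District of Columbia",
             "Florida", "Georgia", "Kentucky", "Louisiana", "Maryland",
             "Mississippi", "North Carolina", "Oklahoma", "South Carolina",
             "Tennessee", "Texas", "Virginia", "West Virginia")
  west <- c("Alaska", "Arizona", "California", "Colorado", "Hawaii", "Idaho",
            "Montana", "Nevada", "New Mexico", "Oregon", "Utah",
            "Washington", "Wyoming")
  data.frame(
    state = c(midwest, northeast, south, west),
    region = rep(c("Midwest", "Northeast", "South", "West"),
                 c(length(midwest), length(northeast), length(south),
                   length(west))),
    stringsAsFactors = FALSE
  )
}

#' Map a US state (or DC) to its census region
#' @param us_state_name character vector of state names.
#' @return character vector of regions (`Midwest`, `Northeast`, `South`,
#'   `West`); unknown names are an error.
#' @export
map_state_to_region <- function(us_state_name) {
  tab <- us_state_regions()
  idx <- match(us_state_name, tab$state)
  bad <- is.na(idx) & !is.na(us_state_name)
  if (any(bad)) {
    stop("unknown US state name(s): ",
         paste(unique(us_state_name[bad]), collapse = ", "))
  }
  tab$region[idx]
}

#' Impute missing months in birth and death dates
#'
#' Missing month of birth is taken as June. A missing death month is taken as
#' June unless that precedes a survey participation date in the death year,
#' in which case December is imputed; a recorded death month is moved to
#' December when an interview in the same year falls after it (the recorded
#' month is considered erroneous). Death records without a death year are
#' ignored (no death date).
#'
#' @param birth_year,birth_month birth date components (month may be `NA`).
#' @param death_year,death_month death date components (both may be `NA`).
#' @param interview_m integer month counts of the person's interviews.
#' @return list with `birth_m` and `death_m` integer month counts
#'   (`death_m = NA` when there is no usable death record).
#' @export
impute_dates <- function(birth_year, birth_month, death_year, death_month,
                         interview_m) {
  if (is.na(birth_year)) stop("birth year is required")
  if (is.na(birth_month)) birth_month <- 6L
  birth_m <- as.integer(birth_year) * 12L + as.integer(birth_month) - 1L
  if (is.na(death_year)) {
    return(list(birth_m = birth_m, death_m = NA_integer_))
  }
  if (death_year < birth_year) stop("death year precedes birth year")
  iv <- interview_m[!is.na(interview_m)]
  if (is.na(death_month)) {
    death_month <- 6L
    cand <- as.integer(death_year) * 12L + death_month - 1L
    if (any(iv > cand)) death_month <- 12L
  } else if (any(ym_year(iv) == death_year &
                 iv %% 12L + 1L > death_month)) {
    # conflicting survey participation in the death year
    death_month <- 12L
  }
  list(birth_m = birth_m,
       death_m = as.integer(death_year) * 12L + as.integer(death_month) - 1L)
}

#' Nearest-wave imputation of a time-varying value
#'
#' Each missing entry is filled with the value at the nearest observed wave
#' by wave distance; ties go to the earlier wave (no future information when
#' both donors are equally close).
#'
#' @param values vector with `NA` for missing waves.
#' @return vector with all entries filled.
#' @export
impute_time_varying_nearest <- function(values) {
  obs <- which(!is.na(values))
  if (!length(obs)) {
    stop("all waves missing: person must be excluded, not imputed")
  }
  mis <- which(is.na(values))
  for (i in mis) {
    d <- abs(obs - i)
    best <- obs[d == min(d)]
    values[i] <- values[min(best)]   # earlier wave wins ties
  }
  values
}

#' Longitudinal survey weight assignment
#'
#' Returns the first non-zero cross-sectional weight from a wave taken at age
#' 50 or older; a person with no qualifying wave is ineligible (`NA`).
#'
#' @param weights per-wave cross-sectional weights (non-negative).
#' @param ages per-wave ages in years.
#' @return a single weight, or `NA` if ineligible.
#' @export
assign_longitudinal_weight <- function(weights, ages) {
  if (any(weights < 0, na.rm = TRUE)) stop("negative survey weight")
  ok <- which(!is.na(weights) & weights > 0 & ages >= 50)
  if (!length(ok)) return(NA_real_)
  weights[ok[1]]
}

#' Apply the person-level exclusion rules
#'
#' Drops persons missing any fixed covariate (sex, education, ethnicity,
#' region), persons with a time-varying covariate (arthritis, obesity)
#' missing at all contributing waves, persons without a qualifying
#' longitudinal weight, and persons with no observation at age 50 or older.
#'
#' @param panel coded panel data.frame (pre-exclusion; may contain `NA`s in
#'   the checked columns).
#' @return list with `panel` (retained rows) and `log` (data.frame `id`,
#'   `reason`; one row per excluded person).
#' @export
apply_exclusions <- function(panel) {
  log <- data.frame(id = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (!nrow(panel)) return(list(panel = panel, log = log))
  drop_ids <- character(0)
  add <- function(ids, reason) {
    ids <- setdiff(as.character(ids), drop_ids)
    if (length(ids)) {
      log <<- rbind(log, data.frame(id = ids, reason = reason,
                                    stringsAsFactors = FALSE))
      drop_ids <<- c(drop_ids, ids)
    }
  }
  by_id <- split(panel, factor(panel$id, levels = unique(panel$id)))
  for (fx in c("sex_female", "educ_hs", "ethnicity", "region")) {
    miss <- vapply(by_id, function(d) anyNA(d[[fx]]), logical(1))
    add(names(by_id)[miss], paste0("fixed_covariate:",
                                   sub("sex_female", "sex",
                                       sub("educ_hs", "education", fx))))
  }
  for (tv in c("arthritis", "obese")) {
    participated <- vapply(by_id, function(d) {
      any(!is.na(d[[tv]][d$state != -2]))
    }, logical(1))
    add(names(by_id)[!participated], paste0("time_varying_all_missing:", tv))
  }
  wmiss <- vapply(by_id, function(d) is.na(d$weight[1]) || d$weight[1] <= 0,
                  logical(1))
  add(names(by_id)[wmiss], "no_qualifying_weight")
  none50 <- vapply(by_id, function(d) !any(d$age >= 50), logical(1))
  add(names(by_id)[none50], "no_observation_50plus")
  keep <- !(as.character(panel$id) %in% drop_ids)
  list(panel = panel[keep, , drop = FALSE], log = log)
}

#' Convert a raw answers panel into the analysis-ready coded panel
#'
#' Runs the complete preparation pipeline: date imputation, age computation,
#' health/work classification and state encoding, irreversible arthritis
#' coding, BMI-based obesity (baseline height, per-wave body weight) with
#' nearest-wave imputation, census-region mapping, education binarisation
#' (high-school diploma/GED/higher), longitudinal weight assignment,
#' exclusions, and restriction to observations at age 50 or older.
#' Running the pipeline on an already-coded panel returns it unchanged
#' (preparation is idempotent).
#'
#' @param raw data.frame in the raw dialect (see the panel-format
#'   documentation in [read_panel()]): columns `id`, `interview_date`,
#'   `participated`, `birth_date`, `death_date`, `sex`, `education`,
#'   `ethnicity`, `us_state`, `weight_cs`, `limit_paid_work`,
#'   `limit_housework`, `limit_activities`, `employment`, `arthritis_dx`,
#'   `height`, `body_weight`.
#' @param unit_system `"metric"` (m, kg) or `"us"` (in, lb) for BMI.
#' @return coded panel data.frame with attribute `"exclusions"` (the
#'   exclusion log).
#' @export
prepare_panel <- function(raw, unit_system = "metric") {
  if (all(c("state", "date", "weight") %in% names(raw))) {
    check_panel(raw)
    return(raw)  # already coded; prep is idempotent
  }
  req <- c("id", "interview_date", "participated", "birth_date",
           "death_date", "sex", "education", "ethnicity", "us_state",
           "weight_cs", "limit_paid_work", "limit_housework",
           "limit_activities", "employment", "arthritis_dx", "height",
           "body_weight")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("raw panel missing column(s): ",
                         paste(miss, collapse = ", "))
  part <- as.logical(raw$participated)
  no_date <- is.na(raw$interview_date) | !nzchar(as.character(raw$interview_date))
  if (any(no_date & part)) {
    stop("participated wave(s) without an interview date at row(s) ",
         paste(utils::head(which(no_date & part), 5), collapse = ", "))
  }

  parse_ym_loose <- function(x) {
    x <- as.character(x)
    y <- ifelse(grepl("^\\d{4}", x), as.integer(substr(x, 1, 4)), NA_integer_)
    m <- ifelse(grepl("^\\d{4}-\\d{2}$", x),
                as.integer(substr(x, 6, 7)), NA_integer_)
    list(year = y, month = m)
  }
  iv_m <- rep(NA_integer_, nrow(raw))
  iv_m[!no_date] <- ym_parse(as.character(raw$interview_date)[!no_date])

  out_pieces <- vector("list", 0)
  by_id <- split(seq_len(nrow(raw)), factor(raw$id, levels = unique(raw$id)))
  for (rows in by_id) {
    rows <- rows[order(iv_m[rows])]
    if (anyDuplicated(iv_m[rows][!is.na(iv_m[rows])])) {
      stop("duplicate interview dates for id ", raw$id[rows[1]])
    }
    b <- parse_ym_loose(raw$birth_date[rows[1]])
    d <- parse_ym_loose(raw$death_date[rows[1]])
    dt <- impute_dates(b$year, b$month, d$year, d$month,
                       iv_m[rows][part[rows]])
    age <- ifelse(is.na(iv_m[rows]), NA_real_, ym_age(dt$birth_m, iv_m[rows]))
    if (any(age < 0, na.rm = TRUE)) {
      stop("birth date after an interview for id ", raw$id[rows[1]])
    }
    health <- classify_health(raw$limit_paid_work[rows],
                              raw$limit_housework[rows],
                              raw$limit_activities[rows])
    work <- classify_work(raw$employment[rows])
    vital <- ifelse(part[rows], "alive", "unknown")
    state <- encode_state(health, work, vital)
    arth <- tryCatch(
      enforce_arthritis_irreversibility(
        replace(as.character(raw$arthritis_dx[rows]), !part[rows],
                NA_character_)),
      error = function(e) rep(NA_integer_, length(rows)))
    h0 <- raw$height[rows]
    h0 <- h0[!is.na(h0)][1]  # baseline height
    ob_raw <- compute_bmi_obesity(rep(h0, length(rows)),
                                  raw$body_weight[rows], unit_system)
    ob_raw[!part[rows]] <- NA_integer_
    obese <- tryCatch(impute_time_varying_nearest(ob_raw),
                      error = function(e) rep(NA_integer_, length(rows)))
    region <- tryCatch(map_state_to_region(as.character(raw$us_state[rows[1]])),
                       error = function(e) NA_character_)
    sex <- as.character(raw$sex[rows[1]])
    sexf <- if (is.na(sex)) NA_integer_ else {
      if (!sex %in% c("male", "female")) stop("sex must be male/female/NA")
      as.integer(sex == "female")
    }
    edu <- as.character(raw$education[rows[1]])
    educ_hs <- if (is.na(edu)) NA_integer_ else {
      as.integer(edu %in% c("high school diploma", "GED",
                            "college or higher"))
    }
    eth <- as.character(raw$ethnicity[rows[1]])
    if (!is.na(eth) && !eth %in% c("Black or African American", "White",
                                   "other")) {
      stop("ethnicity must be 'Black or African American', 'White' or 'other'")
    }
    lw <- assign_longitudinal_weight(
      replace(raw$weight_cs[rows], is.na(raw$weight_cs[rows]), 0), age)
    out_rows <- data.frame(
      id = raw$id[rows],
      date = ifelse(is.na(iv_m[rows]), "", ym_format(iv_m[rows])),
      age = age,
      state = state,
      arthritis = arth,
      obese = obese,
      sex_female = sexf,
      educ_hs = educ_hs,
      ethnicity = eth,
      region = region,
      weight = lw,
      birth_date = ym_format(dt$birth_m),
      death_date = ym_format(dt$death_m),
      stringsAsFactors = FALSE
    )
    out_pieces[[length(out_pieces) + 1L]] <- out_rows
  }
  out <- do.call(rbind, out_pieces)
  # only waves at age >= 50 contribute (skipped waves have no age: keep them
  # between retained waves, they carry the -2 code)
  drop_young <- !is.na(out$age) & out$age < 50
  out <- out[!drop_young, , drop = FALSE]
  ex <- apply_exclusions(out)
  panel <- ex$panel
  rownames(panel) <- NULL
  attr(panel, "exclusions") <- ex$log
  panel
}
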
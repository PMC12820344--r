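# Panel file formats.
#
# Coded-panel CSV dialect (one row per person-wave):
#   id          integer person id
#   date        interview date "YYYY-MM" ("" for skipped waves without one)
#   age         fractional age in years at interview (NA for skipped waves)
#   state       1..4, -1 (alive, state unknown), -2 (wave not participated)
#   arthritis   0/1 (NA at -2 waves)
#   obese       0/1 (NA at -2 waves)
#   sex_female  0/1
#   educ_hs     0/1 (high-school diploma/GED/higher)
#   ethnicity   "black"/"white"/"other" or the printed labels
#   region      Midwest/Northeast/South/West
#   weight      positive longitudinal survey weight (constant per person)
#   birth_date  "YYYY-MM"
#   death_date  "YYYY-MM" or "" when the person is not known to have died

panel_io_cols <- c("id", "date", "age", "state", "arthritis", "obese",
                   "sex_female", "educ_hs", "ethnicity", "region", "weight",
                   "birth_date", "death_date")

#' Write a coded panel (or cohort) to CSV
#'
#' @param cohort an `hwle_cohort` or a coded panel data.frame.
#' @param path output file path.
#' @return `path`, invisibly. Round-trips through [read_panel()].
#' @export
write_panel <- function(cohort, path) {
  panel <- if (inherits(cohort, "hwle_cohort")) cohort$panel else cohort
  miss <- setdiff(panel_io_cols, names(panel))
  if (length(miss)) stop("panel missing column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(panel[panel_io_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a coded panel from CSV
#'
#' Validates the dialect documented in [write_panel()]; malformed rows raise
#' an error naming the row and column.
#'
#' @param path CSV file path.
#' @return coded panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(
                             id = "integer", date = "character",
                             age = "numeric", state = "integer",
                             arthritis = "integer", obese = "integer",
                             sex_female = "integer", educ_hs = "integer",
                             ethnicity = "character", region = "character",
                             weight = "numeric", birth_date = "character",
                             death_date = "character"))
  miss <- setdiff(panel_io_cols, names(panel))
  if (length(miss)) stop("panel file missing column(s): ",
                         paste(miss, collapse = ", "))
  panel$death_date[is.na(panel$death_date)] <- ""
  panel$date[is.na(panel$date)] <- ""
  if (nrow(panel)) {
    bad <- which(!panel$state %in% c(-2, -1, 1:4))
    if (length(bad)) stop("malformed state code at row ", bad[1],
                          ", column 'state'")
    for (col in c("date", "birth_date", "death_date")) {
      x <- panel[[col]]
      bad <- which(nzchar(x) & !grepl("^\\d{4}-\\d{2}$", x))
      if (length(bad)) stop("malformed date at row ", bad[1],
                            ", column '", col, "'")
    }
    bad <- which(!is.na(panel$weight) & panel$weight < 0)
    if (length(bad)) stop("malformed (negative) weight at row ", bad[1],
                          ", column 'weight'")
  }
  panel
}

#' Export a panel in the reference interpolated-Markov-chain input dialect
#'
#' One line per person with fixed-order fields: id, weight, covariate values,
#' birth month/year, death month/year, then one date-state pair per wave.
#' Dates are "mm/yyyy", with "99/9999" for unknown dates; skipped waves carry
#' state -2 at the scheduled date when known. This export exists for
#' cross-validation against the reference estimation program and is not read
#' back by this package.
#'
#' @param cohort an `hwle_cohort` or coded panel data.frame.
#' @param path output file path.
#' @param covariates covariate columns to include (default arthritis).
#' @return `path`, invisibly.
#' @export
write_imach <- function(cohort, path, covariates = "arthritis") {
  panel <- if (inherits(cohort, "hwle_cohort")) cohort$panel else cohort
  fmt <- function(ym_chr) {
    ifelse(nzchar(ym_chr),
           sprintf("%02d/%04d",
                   as.integer(substr(ym_chr, 6, 7)),
                   as.integer(substr(ym_chr, 1, 4))),
           "99/9999")
  }
  lines <- character(0)
  for (d in split(panel, factor(panel$id, levels = unique(panel$id)))) {
    d <- d[order(d$date), , drop = FALSE]
    covs <- vapply(covariates, function(cv) {
      v <- d[[cv]][!is.na(d[[cv]])]
      if (length(v)) v[1] else 0L
    }, numeric(1))
    pairs <- paste(fmt(d$date), d$state, collapse = " ")
    lines <- c(lines, paste(d$id[1], format(d$weight[1]),
                            paste(covs, collapse = " "),
                            fmt(d$birth_date[1]), fmt(d$death_date[1]),
                            pairs))
  }
  writeLines(lines, path)
  invisible(path)
}
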
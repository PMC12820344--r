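# Month-resolution date arithmetic. Dates travel through the package as
# "YYYY-MM" strings; internally they are integer month counts (year * 12 +
# month - 1) so that wave spacing and interpolation steps are exact.

#' Parse "YYYY-MM" dates to integer month counts
#'
#' @param x character vector of dates in `"YYYY-MM"` format (a bare `"YYYY"`
#'   is parsed with a missing month). Empty strings and `NA` give `NA`.
#' @return integer vector of months since year 0 (`year * 12 + month - 1`).
#'   For year-only inputs the month component is `NA`.
#' @keywords internal
#' @export
ym_parse <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nzchar(x)
  full <- ok & grepl("^\\d{4}-\\d{2}$", x)
  yronly <- ok & grepl("^\\d{4}$", x)
  bad <- ok & !full & !yronly
  if (any(bad)) {
    stop("malformed date(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected YYYY-MM)")
  }
  if (any(full)) {
    y <- as.integer(substr(x[full], 1, 4))
    m <- as.integer(substr(x[full], 6, 7))
    if (any(m < 1 | m > 12)) stop("month outside 1-12 in date(s)")
    out[full] <- y * 12L + m - 1L
  }
  # year-only: month unknown, encode as NA but keep the year retrievable
  # via ym_year() on a separate path in the prep module.
  out
}

#' Format integer month counts as "YYYY-MM"
#' @param m integer month count (see [ym_parse()]); `NA` gives `""`.
#' @return character vector.
#' @keywords internal
#' @export
ym_format <- function(m) {
  out <- rep("", length(m))
  ok <- !is.na(m)
  out[ok] <- sprintf("%04d-%02d", m[ok] %/% 12L, m[ok] %% 12L + 1L)
  out
}

ym_year <- function(m) ifelse(is.na(m), NA_integer_, m %/% 12L)

#' Exact fractional age in years between two month-resolution dates
#'
#' Both dates are anchored to day 15 of their month and the difference in
#' days is divided by 365.25, so ages are exact fractional years at month
#' resolution (the data never carry days).
#'
#' @param birth_m,obs_m integer month counts from [ym_parse()].
#' @return numeric age in years.
#' @keywords internal
#' @export
ym_age <- function(birth_m, obs_m) {
  as.numeric(ym_date(obs_m) - ym_date(birth_m)) / 365.25
}

ym_date <- function(m) {
  as.Date(sprintf("%04d-%02d-15", m %/% 12L, m %% 12L + 1L))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
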
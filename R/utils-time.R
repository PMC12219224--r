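# Monthly time-axis helpers. A FieldSeries time axis is a Date vector of
# first-of-month stamps, strictly increasing, no duplicate months.

#' Sequence of calendar months
#'
#' @param start first month, `"YYYY-MM"` string or a `Date`
#' @param n number of months
#' @return `Date` vector of first-of-month stamps
#' @export
month_seq <- function(start, n) {
  if (is.character(start)) start <- as.Date(paste0(start, "-01"))
  seq(as.Date(start), by = "month", length.out = n)
}

#' Decimal years at month centers
#'
#' Converts first-of-month stamps to decimal years at the middle of each
#' month (year + (month - 0.5)/12), the time coordinate used for trend fits.
#'
#' @param time `Date` vector of first-of-month stamps
#' @return numeric vector of decimal years
#' @export
decimal_years <- function(time) {
  y <- as.integer(format(time, "%Y"))
  m <- as.integer(format(time, "%m"))
  y + (m - 0.5) / 12
}

#' True calendar days in each month
#'
#' @param time `Date` vector of first-of-month stamps
#' @return integer vector of day counts (leap Februaries included)
#' @export
days_in_month <- function(time) {
  nxt <- seq_along(time)
  sapply(time, function(d) {
    as.integer(seq(d, by = "month", length.out = 2)[2] - d)
  })
}

month_of <- function(time) as.integer(format(time, "%m"))
year_of <- function(time) as.integer(format(time, "%Y"))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
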
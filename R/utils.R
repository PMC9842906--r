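#' Calendar span in days
#'
#' Number of days from one date to another (`to - from`); e.g. July 7th to
#' September 10th of the same year spans 65 days.
#'
#' @param from,to Dates (or strings coercible to Date).
#' @return Integer number of days.
#' @export
span_days <- function(from, to) {
  as.integer(as.Date(to) - as.Date(from))
}

#' Day of year of a date
#'
#' @param date Date (or string coercible to Date). January 1st is day 1.
#' @return Integer day of year.
#' @export
day_of_year <- function(date) {
  date <- as.Date(date)
  as.integer(date - as.Date(paste0(format(date, "%Y"), "-01-01"))) + 1L
}

#' Date from a year and (possibly fractional) day of year
#'
#' @param year Calendar year.
#' @param doy Day of year (1-based); fractions are floored.
#' @return Date.
#' @export
date_from_doy <- function(year, doy) {
  as.Date(paste0(year, "-01-01")) + floor(doy) - 1L
}
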
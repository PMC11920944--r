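# 365-day ("noleap") calendar helpers and the 24-day period calendar.
#
# The whole pipeline runs on fixed 365-day years: MODIS-style compositing and
# the 24-day period bookkeeping (15 periods per year, period 15 absorbing the
# year remainder) never reference Feb 29, and debt integration uses 365-day
# landfall-anniversary years. Real-calendar input is mapped onto this axis by
# dropping Feb 29, the convention used by noleap climate-model calendars.

#' Build the 24-day period calendar
#'
#' Tiles each requested calendar year with 24-day periods starting January 1.
#' Periods 1--14 are 24 days; period 15 absorbs the remainder of the 365-day
#' year (29 days). Periods tile the year exactly with no overlap.
#'
#' @param years Integer vector of calendar years.
#' @param period_length Days per period (default 24).
#'
#' @return A tibble with one row per period: `year`, `period`, `start_doy`,
#'   `end_doy` (inclusive, day-of-year 1--365), `n_days`, `start_date`,
#'   `end_date`.
#' @export
#' @examples
#' cal <- build_periods(2018)
#' cal[cal$period == 1, ]  # Jan 1 - Jan 24
build_periods <- function(years, period_length = 24L) {
  stopifnot(length(years) >= 1, all(years == as.integer(years)))
  years <- sort(unique(as.integer(years)))
  n_per_year <- max(1L, 365L %/% period_length)  # 15 for 24-day periods
  per_year <- function(y) {
    start_doy <- seq(1L, by = period_length, length.out = n_per_year)
    end_doy <- c(start_doy[-1L] - 1L, 365L)
    tibble::tibble(
      year = y, period = seq_len(n_per_year),
      start_doy = start_doy, end_doy = end_doy,
      n_days = end_doy - start_doy + 1L,
      start_date = noleap_date(y, start_doy),
      end_date = noleap_date(y, end_doy)
    )
  }
  dplyr::bind_rows(lapply(years, per_year))
}

#' Period index of a day of year
#'
#' @param doy Day of year (1--365).
#' @param period_length Days per period (default 24).
#' @return Integer period index in 1--15.
#' @export
period_of_doy <- function(doy, period_length = 24L) {
  stopifnot(all(doy >= 1 & doy <= 365))
  n_per_year <- max(1L, 365L %/% period_length)
  pmin((as.integer(doy) - 1L) %/% period_length + 1L, n_per_year)
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Convert a (year, day-of-year) pair on the 365-day calendar to a Date
#'
#' Day-of-year 60 and later skip Feb 29 in leap years, so `noleap_date(y, 60)`
#' is always March 1.
#'
#' @param year Calendar year.
#' @param doy Day of year on the 365-day calendar (1--365).
#' @return A `Date` vector.
#' @export
noleap_date <- function(year, doy) {
  stopifnot(all(doy >= 1 & doy <= 365))
  skip <- as.integer(is_leap_year(year) & doy >= 60)  # Mar 1 onward shifts
  as.Date(doy - 1 + skip, origin = paste0(year, "-01-01"))
}

#' Day-of-year on the 365-day calendar
#'
#' Feb 29 maps to NA; later days in leap years shift down by one so that
#' Dec 31 is always day 365.
#'
#' @param date A `Date` vector.
#' @return Integer day of year (1--365), NA for Feb 29.
#' @export
noleap_doy <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  leap <- is_leap_year(as.integer(format(date, "%Y")))
  out <- doy
  out[leap & doy == 60] <- NA_integer_
  out[leap & doy > 60] <- doy[leap & doy > 60] - 1L
  out
}

# Days between two dates on the 365-day calendar (excludes any Feb 29 in
# [from, to)). Used to place hurricane landfall on the simulation time axis.
noleap_diff <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  n <- as.numeric(to - from)
  yrs <- seq(as.integer(format(from, "%Y")), as.integer(format(to, "%Y")))
  leaps <- yrs[is_leap_year(yrs)]
  if (length(leaps)) {
    feb29 <- as.Date(paste0(leaps, "-02-29"))
    n <- n - sum(feb29 >= from & feb29 < to)
  }
  n
}
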
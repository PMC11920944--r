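# Quality filtering, day/night splitting, LAI compositing and gap-filling.

check_flux <- function(series, cols = c("time", "nee", "rg", "tair")) {
  if (!is.data.frame(series) || nrow(series) == 0)
    stop("flux series must be a non-empty data frame")
  missing_cols <- setdiff(cols, names(series))
  if (length(missing_cols))
    stop("flux series lacks columns: ", paste(missing_cols, collapse = ", "))
  invisible(series)
}

#' Range-filter half-hourly NEE
#'
#' Flags NEE outside the expected physical range (default beyond +/-100 umol
#' CO2 m-2 s-1) as `range_removed`; such records are excluded from all fits
#' but their values are preserved. Filtering is idempotent.
#'
#' @param series Flux tibble with at least `nee` (and a `qc` column, created
#'   if absent).
#' @param lo,hi Range bounds (defaults -100, 100); values strictly outside
#'   `[lo, hi]` are removed.
#' @return The series with an updated `qc` column.
#' @export
filter_range <- function(series, lo = -100, hi = 100) {
  check_flux(series, "nee")
  if (lo >= hi) stop("lo must be < hi")
  if (!"qc" %in% names(series))
    series$qc <- ifelse(is.na(series$nee), "missing", "ok")
  out <- !is.na(series$nee) & (series$nee < lo | series$nee > hi)
  series$qc[out] <- "range_removed"
  series
}

# Records usable for fitting.
flux_ok <- function(series) series$qc == "ok" & !is.na(series$nee)

#' Split records into daytime and nighttime by shortwave radiation
#'
#' Daytime is strict `rg > threshold`; nighttime is `rg <= threshold`
#' (records at exactly the threshold go to night, the conservative choice for
#' light-response fitting). Records with missing `rg` belong to neither mask.
#'
#' @param series Flux tibble with an `rg` column (W m-2).
#' @param rg_threshold Day/night threshold (default 50 W m-2).
#' @return A list with logical vectors `day` and `night`.
#' @export
split_daynight <- function(series, rg_threshold = 50) {
  check_flux(series, "rg")
  if (all(is.na(series$rg))) stop("all rg values are missing")
  has <- !is.na(series$rg)
  list(day = has & series$rg > rg_threshold,
       night = has & series$rg <= rg_threshold)
}

#' Composite an 8-day LAI series to 24-day period maxima
#'
#' For each calendar period, takes the maximum over all 8-day values whose
#' composite start date falls inside the period (reduces MODIS-style noise
#' and gaps). Periods with no usable value are missing. If the input carries
#' a logical `qa_pass` column, failing samples are dropped first.
#'
#' @param lai8 Tibble with `year`, `doy`, `lai` (and optional `qa_pass`).
#' @param calendar Period calendar from [build_periods()].
#' @return The calendar with `lai` (NA where no data) and `filled = FALSE`.
#' @export
composite_lai <- function(lai8, calendar) {
  stopifnot(all(c("year", "doy", "lai") %in% names(lai8)))
  if ("qa_pass" %in% names(lai8)) lai8 <- lai8[lai8$qa_pass %in% TRUE, ]
  lai8 <- lai8[!is.na(lai8$lai), ]
  lai8$period <- period_of_doy(lai8$doy)
  agg <- dplyr::summarise(dplyr::group_by(lai8, .data$year, .data$period),
                          lai = max(.data$lai), .groups = "drop")
  out <- dplyr::left_join(calendar, agg, by = c("year", "period"))
  out$filled <- FALSE
  out
}

#' Linearly gap-fill a composited LAI series
#'
#' Interior gaps of at most `max_gap` consecutive missing periods are filled
#' by linear interpolation (in period index) between the flanking observed
#' values and flagged `filled`; longer gaps and leading/trailing gaps are
#' left missing (interpolation needs two anchors; no extrapolation).
#'
#' @param lai_series Tibble from [composite_lai()] ordered by year and
#'   period, with columns `lai` and `filled`.
#' @param max_gap Maximum gap length to fill, in periods (>= 0).
#' @return The series with gaps filled and flagged.
#' @export
gapfill_linear <- function(lai_series, max_gap) {
  stopifnot(all(c("lai", "filled") %in% names(lai_series)))
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (sum(!is.na(lai_series$lai)) < 2) {
    warning("fewer than 2 observed LAI values; returning unchanged")
    return(lai_series)
  }
  if (max_gap == 0) return(lai_series)
  filled_vals <- zoo::na.approx(lai_series$lai, x = seq_len(nrow(lai_series)),
                                maxgap = max_gap, na.rm = FALSE)
  newly <- is.na(lai_series$lai) & !is.na(filled_vals)
  lai_series$lai <- filled_vals
  lai_series$filled <- lai_series$filled | newly
  lai_series
}

#' Per-period data coverage under a mask
#'
#' Coverage of a period is the number of usable records (passing QC, NEE
#' present) within the mask divided by the number of half-hourly grid records
#' in the period belonging to the mask. The denominator is mask-specific
#' because the 40% availability rule gates the daytime and nighttime fits
#' separately.
#'
#' @param series Full-grid flux tibble (missing records present with
#'   `nee = NA`), with `year`, `doy`, `nee`, `qc`.
#' @param calendar Period calendar from [build_periods()].
#' @param mask Optional logical vector over records (e.g. the day mask);
#'   default all records.
#' @return The calendar with `n_expected`, `n_ok`, `coverage` in `[0, 1]`.
#' @export
period_coverage <- function(series, calendar, mask = NULL) {
  check_flux(series, c("year", "doy", "nee", "qc"))
  if (is.null(mask)) mask <- rep(TRUE, nrow(series))
  per <- period_of_doy(series$doy)
  key <- paste(series$year, per)
  cal_key <- paste(calendar$year, calendar$period)
  ok <- flux_ok(series)
  n_expected <- as.vector(table(factor(key[mask], levels = cal_key)))
  n_ok <- as.vector(table(factor(key[mask & ok], levels = cal_key)))
  out <- calendar
  out$n_expected <- n_expected
  out$n_ok <- n_ok
  out$coverage <- ifelse(n_expected > 0, n_ok / n_expected, NA_real_)
  out
}
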
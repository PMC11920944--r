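# Relative non-stationarity (RN) impact detection.
#
# For each trailing window of per-period values, an ordinary least-squares
# regression of value on time estimates the change dx = slope * window span;
# RN = dx / window mean. Annual frequencies in the data (the seasonal cycle
# of Tair-driven parameters) are accounted for within the slope computation
# by including annual sine/cosine harmonics as nuisance regressors: a pure
# seasonal cycle spanning whole years then contributes exactly nothing to
# the slope, while a linear trend is recovered exactly.

#' Relative non-stationarity statistic over trailing windows
#'
#' For every complete trailing window of `window_len` consecutive values the
#' statistic is `RN = dx / mean(window)` with `dx` the OLS slope of value on
#' time multiplied by the window time span. Windows containing any missing
#' value are skipped (RN is NA), as are windows whose mean is zero. RN is
#' indexed by the window-end period so post-landfall values reflect data
#' entering the window after the storm.
#'
#' @param time Numeric time of each period (days; typically the period end).
#' @param value Per-period parameter or flux values.
#' @param window_len Window length in periods (default 45, about 3 years of
#'   24-day periods).
#' @param annual_period Period of the seasonal harmonic in time units
#'   (default 365 days); `NULL` disables seasonal adjustment. Harmonics are
#'   only used when the window holds at least 6 points.
#' @return A tibble `time`, `value`, `rn` with `rn` defined from row
#'   `window_len` onwards.
#' @export
rn_statistic <- function(time, value, window_len = 45L,
                         annual_period = 365) {
  stopifnot(length(time) == length(value))
  n <- length(value)
  if (window_len < 3) stop("window_len must be >= 3")
  if (n < window_len) stop("series shorter than window_len")
  use_harmonics <- !is.null(annual_period) && window_len >= 6
  rn <- rep(NA_real_, n)
  for (i in window_len:n) {
    idx <- (i - window_len + 1L):i
    v <- value[idx]
    if (anyNA(v) || anyNA(time[idx])) next
    t <- time[idx]
    x <- cbind(1, t)
    if (use_harmonics)
      x <- cbind(x, sin(2 * pi * t / annual_period),
                 cos(2 * pi * t / annual_period))
    cf <- stats::lm.fit(x, v)$coefficients
    slope <- cf[2]
    if (is.na(slope)) next
    m <- mean(v)
    if (m == 0) next  # undefined RN, flagged as NA
    rn[i] <- slope * (t[window_len] - t[1]) / m
  }
  tibble::tibble(time = time, value = value, rn = rn)
}

#' Impact thresholds from the full-record RN distribution
#'
#' Empirical percentiles (linear-interpolation convention) of `|RN|` over
#' the entire record, used to decide when a variable deviates from
#' stationarity and when it returns.
#'
#' @param rn RN values (NAs ignored); at least 10 defined values required.
#' @param percentiles Percentiles in (0, 100), default `c(85, 90, 95)`.
#' @return Named numeric vector of thresholds, ordered with the input
#'   percentiles (monotone non-decreasing).
#' @export
impact_thresholds <- function(rn, percentiles = c(85, 90, 95)) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must be strictly inside (0, 100)")
  rn <- rn[!is.na(rn)]
  if (length(rn) < 10)
    stop("need at least 10 defined RN values to set thresholds")
  stats::quantile(abs(rn), probs = percentiles / 100, type = 7,
                  names = TRUE)
}

#' Impact duration after landfall at a given threshold
#'
#' The number of days from landfall to the last post-landfall period (within
#' `horizon`) whose `|RN|` exceeds the threshold -- the "last date within the
#' impact threshold". Zero when no post-landfall exceedance occurs. Durations
#' are monotone non-increasing in the threshold.
#'
#' @param time Period end times (days), aligned with `rn`.
#' @param rn RN values from [rn_statistic()].
#' @param landfall Landfall time (same units as `time`).
#' @param threshold Threshold on `|RN|` from [impact_thresholds()].
#' @param horizon Maximum look-ahead after landfall in days (default
#'   unlimited).
#' @return Duration in days (>= 0).
#' @export
impact_duration <- function(time, rn, landfall, threshold,
                            horizon = Inf) {
  stopifnot(length(time) == length(rn))
  hit <- !is.na(rn) & abs(rn) > threshold &
    time > landfall & time <= landfall + horizon
  if (!any(hit)) return(0)
  max(time[hit]) - landfall
}

#' Full impact analysis of one per-period series
#'
#' Computes RN over trailing windows, derives the percentile thresholds from
#' the full record, and extracts the post-landfall impact duration at each
#' threshold.
#'
#' @inheritParams rn_statistic
#' @param landfall Landfall time (days, same axis as `time`).
#' @param percentiles Threshold percentiles (default `c(85, 90, 95)`).
#' @param horizon Look-ahead limit in days for durations (default `Inf`).
#' @return A list of class `impact_series`: `rn` (tibble), `thresholds`
#'   (named vector), `durations` (tibble `percentile, threshold, days`).
#' @export
detect_impacts <- function(time, value, landfall, window_len = 45L,
                           annual_period = 365,
                           percentiles = c(85, 90, 95), horizon = Inf) {
  rn <- rn_statistic(time, value, window_len, annual_period)
  thr <- impact_thresholds(rn$rn, percentiles)
  durations <- tibble::tibble(
    percentile = percentiles,
    threshold = as.numeric(thr),
    days = vapply(thr, function(th)
      impact_duration(rn$time, rn$rn, landfall, th, horizon), numeric(1))
  )
  structure(list(rn = rn, thresholds = thr, durations = durations),
            class = "impact_series")
}
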
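# Recovery-debt accounting: annual and cumulative deficits in NEE relative
# to the pre-disturbance reference, in carbon units.
#
# Sign convention: debt = sum(NEE_post - mean(NEE_pre)). With NEE negative
# for net uptake, a weakened post-storm sink gives positive debt; negative
# values indicate enhanced carbon capture.

MOLAR_MASS_C <- 12.011   # g C per mol
HALF_HOUR_S <- 1800      # seconds per half-hourly record

#' Convert a summed half-hourly CO2 flux to grams of carbon
#'
#' @param nee_sum Sum of half-hourly NEE values (umol CO2 m-2 s-1).
#' @param dt Record duration in seconds (default 1800).
#' @return Carbon flux total in g C m-2.
#' @export
umol_sum_to_gc <- function(nee_sum, dt = HALF_HOUR_S) {
  nee_sum * dt * MOLAR_MASS_C * 1e-6
}

#' Inverse of [umol_sum_to_gc()]
#' @param gc Carbon total in g C m-2.
#' @param dt Record duration in seconds.
#' @return Summed NEE in umol CO2 m-2 s-1.
#' @export
gc_to_umol_sum <- function(gc, dt = HALF_HOUR_S) {
  gc / (dt * MOLAR_MASS_C * 1e-6)
}

#' Pre-disturbance reference NEE
#'
#' Arithmetic mean of half-hourly NEE over the 365 days before landfall
#' (half-open window `[landfall - 365, landfall)`).
#'
#' @param series Tibble with `time` (days) and `nee`.
#' @param landfall Landfall time (days, same axis as `time`).
#' @param min_frac Minimum fraction of the window's half-hours that must be
#'   present (default 0.8).
#' @param dt_days Record spacing in days (default half-hourly, 1/48).
#' @return Mean NEE in umol CO2 m-2 s-1.
#' @export
reference_nee <- function(series, landfall, min_frac = 0.8,
                          dt_days = 1 / 48) {
  check_flux(series, c("time", "nee"))
  if (landfall - 365 < min(series$time) - 1e-9)
    stop("reference window extends before series start")
  win <- series$time >= landfall - 365 & series$time < landfall
  n_expected <- round(365 / dt_days)
  frac <- sum(win & !is.na(series$nee)) / n_expected
  if (frac < min_frac)
    stop(sprintf("only %.0f%% of the pre-landfall year present (need %.0f%%)",
                 100 * frac, 100 * min_frac))
  mean(series$nee[win], na.rm = TRUE)
}

#' Annual recovery debt for one post-landfall year
#'
#' Integrates `(NEE_post - reference)` over landfall-anniversary year `k`
#' (the half-open window `[landfall + (k-1)*365, landfall + k*365)`) and
#' converts to g C m-2. Positive values are carbon debt (weakened sink);
#' negative values are enhanced capture.
#'
#' @param series Tibble with `time` and gap-free `nee` over year `k`
#'   (measured, or modeled NEE when the tower was offline).
#' @param reference Reference NEE from [reference_nee()].
#' @param landfall Landfall time (days).
#' @param year_k Post-landfall year index (1, 2, ...).
#' @param dt Record duration in seconds (default 1800).
#' @return Annual debt in g C m-2.
#' @export
annual_debt <- function(series, reference, landfall, year_k,
                        dt = HALF_HOUR_S) {
  check_flux(series, c("time", "nee"))
  if (year_k < 1 || year_k != as.integer(year_k))
    stop("year_k must be a positive integer")
  win <- series$time >= landfall + (year_k - 1) * 365 &
    series$time < landfall + year_k * 365
  if (!any(win))
    stop("post series does not cover post-landfall year ", year_k)
  if (anyNA(series$nee[win]))
    stop("gaps in the post series for year ", year_k,
         "; supply modeled NEE for offline intervals")
  umol_sum_to_gc(sum(series$nee[win] - reference), dt)
}

#' Cumulative recovery debt
#'
#' Running sum of annual debts for consecutive post-landfall years. The
#' recovery-of-all-lost-carbon year is the first year whose cumulative debt
#' is at or below zero.
#'
#' @param annual Numeric vector of annual debts (g C m-2) for years
#'   1, 2, ... since landfall.
#' @return Tibble `year_since_landfall`, `annual_debt`, `cumulative_debt`
#'   with attribute `recovery_year` (NA if never recovered).
#' @export
cumulative_debt <- function(annual) {
  cum <- cumsum(annual)
  out <- tibble::tibble(year_since_landfall = seq_along(annual),
                        annual_debt = annual, cumulative_debt = cum)
  rec <- which(cum <= 0)
  attr(out, "recovery_year") <- if (length(rec)) rec[1] else NA_integer_
  out
}

#' Site-level recovery debt over the recovery horizon
#'
#' Convenience wrapper: computes the pre-landfall reference and the annual
#' and cumulative debt for each requested year.
#'
#' @inheritParams reference_nee
#' @param years Post-landfall years (default 1:4, the standard recovery
#'   horizon).
#' @param dt Record duration in seconds.
#' @return Tibble as [cumulative_debt()], with attribute `reference_nee`.
#' @export
recovery_debt <- function(series, landfall, years = 1:4, min_frac = 0.8,
                          dt = HALF_HOUR_S) {
  ref <- reference_nee(series, landfall, min_frac)
  annual <- vapply(years, function(k)
    annual_debt(series, ref, landfall, k, dt), numeric(1))
  out <- cumulative_debt(annual)
  out$year_since_landfall <- years
  attr(out, "reference_nee") <- ref
  out
}

#' Aggregate per-pixel debts to landscape totals
#'
#' Converts per-pixel areal debt (g C m-2) to tonnes of carbon per pixel and
#' a landscape total in Mt C, preserving the per-pixel map. Also reports the
#' fraction of pixels with negative (enhanced-capture) debt.
#'
#' @param debts Per-pixel debt in g C m-2.
#' @param areas Per-pixel area in m2 (recycled if length 1).
#' @param pixel_id Optional pixel identifiers.
#' @return A list: `per_pixel` (tibble `pixel_id, debt_gc_m2, tonnes_c`),
#'   `total_mt_c`, `frac_pixels_negative`.
#' @export
landscape_debt <- function(debts, areas, pixel_id = seq_along(debts)) {
  if (length(areas) == 1) areas <- rep(areas, length(debts))
  if (length(areas) != length(debts) || anyNA(areas))
    stop("each pixel debt needs an area")
  tonnes <- debts * areas / 1e6          # g -> t
  list(per_pixel = tibble::tibble(pixel_id = pixel_id,
                                  debt_gc_m2 = debts, tonnes_c = tonnes),
       total_mt_c = sum(tonnes) / 1e6,   # t -> Mt
       frac_pixels_negative = mean(debts < 0))
}

#' Mean and standard error across NEE-estimation variants
#'
#' Summarises debt estimates from the LRC and LRC+TRC reconstruction
#' variants. With a single variant the mean is reported and the SE flagged
#' undefined.
#'
#' @param values Debt estimates, one per variant.
#' @return Tibble `mean`, `se` (NA when undefined), `n`.
#' @export
summarize_variants <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no variant estimates supplied")
  tibble::tibble(mean = mean(values),
                 se = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
                 n = n)
}
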
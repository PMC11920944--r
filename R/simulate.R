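# Synthetic flux-tower and landscape simulator.
#
# Generates half-hourly drivers (Rg, Tair), an 8-day LAI series with a step
# drop at hurricane landfall followed by exponential recovery, half-hourly NEE
# from the Michaelis-Menten light response (day) and Lloyd-Taylor temperature
# response (night) with parameters tied to period-composited LAI, and a
# bimodal-LAI landscape grid. Every piece of ground truth (per-period
# parameters, the disturbance trajectory, the analytically expected recovery
# debt) is returned alongside so downstream stages can be validated exactly.

#' Default mapping from LAI to carbon-exchange parameters
#'
#' Returns a function of LAI giving the five generating parameters. Amax,
#' Reco and rb scale with the saturating light-capture term
#' `(1 - exp(-k * LAI))`, normalised so that at `lai_ref` the parameters equal
#' the tall-forest reference values; QY and E0 are constant. Defaults are the
#' long-term tall-forest means observed in Everglades mangroves
#' (QY = -0.1367 umol/J, Amax = -32.14, LRC Reco = 7.49, rb = 3.22 umol
#' CO2 m-2 s-1, E0 = 107.43) at a reference LAI of 5.55 m2 m-2.
#'
#' @param qy Quantum yield (umol/J, <= 0), constant in LAI.
#' @param amax_ref Light-saturated assimilation at `lai_ref` (umol m-2 s-1, < 0).
#' @param reco_ref Daytime ecosystem respiration at `lai_ref` (>= 0).
#' @param rb_ref Base respiration at Tref at `lai_ref` (>= 0).
#' @param e0 Temperature sensitivity, constant in LAI.
#' @param k Canopy light-capture extinction coefficient (per unit LAI).
#' @param lai_ref Reference LAI at which `*_ref` values apply.
#' @param resp_lai_coupling Fraction of the respiration terms (Reco, rb)
#'   that scales with LAI; 1 (default) couples respiration fully to canopy
#'   light capture, 0 leaves respiration at its reference value regardless
#'   of defoliation (heterotrophic respiration from litterfall continuing
#'   after canopy loss).
#'
#' @return A function `f(lai)` returning a tibble with columns
#'   `qy, amax, reco, rb, e0`.
#' @export
#' @examples
#' law <- default_param_law()
#' law(c(2.87, 5.55))
default_param_law <- function(qy = -0.1367, amax_ref = -32.14,
                              reco_ref = 7.49, rb_ref = 3.22, e0 = 107.43,
                              k = 0.5, lai_ref = 5.55,
                              resp_lai_coupling = 1) {
  norm <- 1 - exp(-k * lai_ref)
  function(lai) {
    s <- (1 - exp(-k * lai)) / norm
    s_resp <- (1 - resp_lai_coupling) + resp_lai_coupling * s
    tibble::tibble(
      qy = rep(qy, length(lai)),
      amax = amax_ref * s,
      reco = reco_ref * s_resp,
      rb = rb_ref * s_resp,
      e0 = rep(e0, length(lai))
    )
  }
}

#' Log-linear parameter law from the landscape-scaling family
#'
#' A parameter law whose magnitudes are log-linear in LAI,
#' `|y| = exp(b0 + b1 * LAI)` -- the same functional family as the
#' exponential landscape-scaling model -- anchored so that Amax passes
#' through the tall-forest and scrub reference values. Respiration terms use
#' a weak LAI slope (`resp_slope`), reflecting heterotrophic respiration
#' that persists after defoliation. Useful for end-to-end validation of the
#' scaling pipeline against a generating law it can represent exactly.
#'
#' @param qy Constant quantum yield.
#' @param amax_anchors Two `c(lai, amax)` anchor pairs as a 2x2 matrix-like
#'   list; default tall (5.55, -32.14) and scrub (2.87, -9.97).
#' @param reco_ref,rb_ref Respiration magnitudes at `lai_ref`.
#' @param resp_slope Log-linear LAI slope of the respiration terms.
#' @param e0 Constant temperature sensitivity.
#' @param lai_ref Reference LAI for the respiration anchors.
#' @return A function `f(lai)` returning a tibble `qy, amax, reco, rb, e0`.
#' @export
scaling_family_param_law <- function(qy = -0.1367,
                                     amax_anchors = list(c(5.55, -32.14),
                                                         c(2.87, -9.97)),
                                     reco_ref = 7.49, rb_ref = 3.22,
                                     resp_slope = 0.1, e0 = 107.43,
                                     lai_ref = 5.55) {
  a1 <- amax_anchors[[1]]; a2 <- amax_anchors[[2]]
  b1 <- log(abs(a1[2]) / abs(a2[2])) / (a1[1] - a2[1])
  b0 <- log(abs(a1[2])) - b1 * a1[1]
  c0 <- log(reco_ref) - resp_slope * lai_ref
  d0 <- log(rb_ref) - resp_slope * lai_ref
  function(lai) {
    tibble::tibble(
      qy = rep(qy, length(lai)),
      amax = -exp(b0 + b1 * lai),
      reco = exp(c0 + resp_slope * lai),
      rb = exp(d0 + resp_slope * lai),
      e0 = rep(e0, length(lai))
    )
  }
}

#' Configuration for the synthetic flux tower
#'
#' Defines the simulated study: a multi-year half-hourly record with a single
#' hurricane landfall, LAI dropping by `lai_drop_frac` at landfall and
#' recovering exponentially with e-folding time `lai_recovery_days`
#' (optionally overshooting the pre-storm baseline during regrowth), and NEE
#' generated from the light/temperature response curves with parameters tied
#' to LAI through `param_law`.
#'
#' @param start_date First simulated day; must be a January 1.
#' @param n_years Number of simulated 365-day years (>= 1).
#' @param landfall_date Hurricane landfall; must lie inside the simulated span.
#' @param lai_baseline Pre-disturbance LAI (m2 m-2, > 0).
#' @param lai_drop_frac Fraction of LAI lost at landfall, in `[0, 1]`.
#' @param lai_recovery_days E-folding time of LAI recovery (days).
#' @param lai_overshoot_frac Asymptotic fractional LAI overshoot above the
#'   baseline during regrowth (default 0 = recovery exactly to baseline).
#' @param lai_overshoot_days E-folding time of the overshoot term (days).
#' @param lai_noise_sd SD of additive Gaussian noise on the 8-day LAI samples.
#' @param param_law Function mapping LAI to generating parameters; see
#'   [default_param_law()].
#' @param noise_sd SD of additive Gaussian noise on half-hourly NEE
#'   (umol CO2 m-2 s-1, >= 0).
#' @param missing_frac Fraction of NEE records removed uniformly at random,
#'   in `[0, 1)`.
#' @param outage Optional length-2 numeric vector of day offsets
#'   `c(from, to)`: all NEE in `[from, to)` is removed (tower offline).
#' @param tair_mean Annual-mean air temperature (degC).
#' @param tair_seasonal_amp,tair_diurnal_amp Seasonal and diurnal Tair
#'   amplitudes (degC).
#' @param rg_peak Clear-sky solar noon shortwave maximum (W m-2).
#' @param rg_threshold Day/night split used generatively (W m-2).
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(start_date = "2015-01-01", n_years = 7L,
                       landfall_date = "2017-09-10",
                       lai_baseline = 5.55, lai_drop_frac = 0.4,
                       lai_recovery_days = 90,
                       lai_overshoot_frac = 0, lai_overshoot_days = 500,
                       lai_noise_sd = 0,
                       param_law = default_param_law(),
                       noise_sd = 2, missing_frac = 0.25, outage = NULL,
                       tair_mean = 25, tair_seasonal_amp = 4,
                       tair_diurnal_amp = 5, rg_peak = 900,
                       rg_threshold = 50, seed = 1L) {
  start_date <- as.Date(start_date)
  landfall_date <- as.Date(landfall_date)
  if (format(start_date, "%m-%d") != "01-01")
    stop("start_date must be a January 1 (periods are keyed to calendar years)")
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1 ||
      n_years != as.integer(n_years))
    stop("n_years must be a positive integer")
  if (lai_baseline <= 0) stop("lai_baseline must be > 0")
  if (lai_drop_frac < 0 || lai_drop_frac > 1)
    stop("lai_drop_frac must be in [0, 1]")
  if (lai_recovery_days <= 0) stop("lai_recovery_days must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  if (!is.function(param_law)) stop("param_law must be a function of LAI")
  landfall_day <- noleap_diff(start_date, landfall_date)
  if (landfall_day < 0 || landfall_day >= n_years * 365)
    stop("landfall_date must lie within the simulated span")
  structure(list(
    start_date = start_date, n_years = as.integer(n_years),
    landfall_date = landfall_date, landfall_day = landfall_day,
    lai_baseline = lai_baseline, lai_drop_frac = lai_drop_frac,
    lai_recovery_days = lai_recovery_days,
    lai_overshoot_frac = lai_overshoot_frac,
    lai_overshoot_days = lai_overshoot_days,
    lai_noise_sd = lai_noise_sd, param_law = param_law,
    noise_sd = noise_sd, missing_frac = missing_frac, outage = outage,
    tair_mean = tair_mean, tair_seasonal_amp = tair_seasonal_amp,
    tair_diurnal_amp = tair_diurnal_amp, rg_peak = rg_peak,
    rg_threshold = rg_threshold, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_years <- function(config) {
  y0 <- as.integer(format(config$start_date, "%Y"))
  seq(y0, y0 + config$n_years - 1L)
}

#' Simulate half-hourly radiation and air temperature drivers
#'
#' Deterministic clear-sky-like diurnal/seasonal shortwave and sinusoidal air
#' temperature on the half-hourly 365-day grid. Rg is zero at local midnight
#' (and all night); the discrete annual and diurnal Tair cycles average to
#' `tair_mean` exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with `time` (days since series start), `year`, `doy`,
#'   `hod` (hour of day), `rg` (W m-2), `tair` (degC); one row per half hour,
#'   `n_years * 365 * 48` rows in total.
#' @export
simulate_drivers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_days <- config$n_years * 365L
  day <- rep(0:(n_days - 1L), each = 48L)
  hod <- rep(seq(0, 23.5, by = 0.5), times = n_days)
  doy <- day %% 365L + 1L
  year <- sim_years(config)[day %/% 365L + 1L]
  seasonal <- 1 + 0.15 * cos(2 * pi * (doy - 172) / 365)
  rg <- config$rg_peak * seasonal * pmax(0, cos(pi * (hod - 12) / 12))
  tair <- config$tair_mean +
    config$tair_seasonal_amp * cos(2 * pi * (doy - 207) / 365) +
    config$tair_diurnal_amp * cos(2 * pi * (hod - 15) / 24)
  tibble::tibble(time = day + hod / 24, year = year, doy = doy, hod = hod,
                 rg = rg, tair = tair)
}

# Deterministic LAI trajectory at day offsets `t`, for an arbitrary baseline.
# Pre-landfall: baseline. At landfall the canopy loses `drop_frac` of its leaf
# area, then refoliates with e-folding time `recovery_days`; an optional
# overshoot term lets regrowth exceed the pre-storm baseline.
lai_curve <- function(t, baseline, landfall_day, drop_frac, recovery_days,
                      overshoot_frac = 0, overshoot_days = 500) {
  dt <- t - landfall_day
  post <- dt >= 0
  lai <- rep(baseline, length(t))
  lai[post] <- baseline *
    (1 + overshoot_frac * (1 - exp(-dt[post] / overshoot_days))) -
    baseline * drop_frac * exp(-dt[post] / recovery_days)
  lai
}

#' Simulate the 8-day LAI series
#'
#' Samples the disturbance LAI trajectory every 8 days (the MODIS composite
#' cadence): constant at `lai_baseline` before landfall, stepping down to
#' `lai_baseline * (1 - lai_drop_frac)` at landfall, then recovering as
#' `baseline - drop * exp(-dt / lai_recovery_days)`.
#'
#' @param config A [sim_config()].
#' @return A tibble with `time` (day offset of the composite start), `year`,
#'   `doy`, `date`, and `lai` (m2 m-2, truncated at 0).
#' @export
simulate_lai <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t <- seq(0, config$n_years * 365L - 1L, by = 8L)
  lai <- lai_curve(t, config$lai_baseline, config$landfall_day,
                   config$lai_drop_frac, config$lai_recovery_days,
                   config$lai_overshoot_frac, config$lai_overshoot_days)
  if (config$lai_noise_sd > 0) {
    set.seed(config$seed + 1L)
    lai <- lai + stats::rnorm(length(lai), 0, config$lai_noise_sd)
  }
  lai <- pmax(lai, 0)
  doy <- t %% 365L + 1L
  year <- sim_years(config)[t %/% 365L + 1L]
  tibble::tibble(time = as.numeric(t), year = year, doy = doy,
                 date = noleap_date(year, doy), lai = lai)
}

# Per-period generating parameters: the period LAI is the maximum of the
# 8-day samples whose composite start falls in the period (the same
# compositing the analysis pipeline applies), and parameters are constant
# within a period so that refitting noise-free data recovers them exactly.
period_truth <- function(config, lai8 = NULL) {
  if (is.null(lai8)) lai8 <- simulate_lai(config)
  cal <- build_periods(sim_years(config))
  comp <- composite_lai(lai8, cal)
  pars <- config$param_law(comp$lai)
  dplyr::bind_cols(comp[c("year", "period", "start_doy", "end_doy", "lai")],
                   pars)
}

#' Simulate a half-hourly flux-tower record with known truth
#'
#' Generates NEE from the light response curve (daytime, Rg above the
#' day/night threshold) and the temperature response curve (nighttime) with
#' per-period parameters given by `param_law` applied to the
#' period-composited LAI, plus additive iid Gaussian noise. A fraction of
#' NEE records is removed uniformly at random, and an optional outage window
#' removes a contiguous block (tower offline after a storm).
#'
#' @param config A [sim_config()].
#' @return A list of class `tower_sim` with elements
#'   \describe{
#'     \item{series}{half-hourly flux tibble: `time, year, doy, hod, nee, rg,
#'       tair, qc` (`qc` is `"ok"` or `"missing"`; missing records keep their
#'       drivers but have `nee = NA`)}
#'     \item{truth}{per-period generating parameters
#'       (`year, period, lai, qy, amax, reco, rb, e0`)}
#'     \item{lai}{the 8-day LAI series}
#'     \item{calendar}{the 24-day period calendar}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_tower <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  drv <- simulate_drivers(config)
  lai8 <- simulate_lai(config)
  truth <- period_truth(config, lai8)
  cal <- build_periods(sim_years(config))

  key <- truth$year * 100L + truth$period
  idx <- match(drv$year * 100L + period_of_doy(drv$doy), key)
  day <- drv$rg > config$rg_threshold
  nee <- ifelse(day,
                predict_lrc(drv$rg, truth$qy[idx], truth$amax[idx],
                            truth$reco[idx]),
                predict_trc(drv$tair, truth$rb[idx], truth$e0[idx]))

  set.seed(config$seed)
  nee <- nee + stats::rnorm(length(nee), 0, config$noise_sd)
  qc <- rep("ok", length(nee))
  if (config$missing_frac > 0) {
    gone <- stats::runif(length(nee)) < config$missing_frac
    nee[gone] <- NA_real_
    qc[gone] <- "missing"
  }
  if (!is.null(config$outage)) {
    off <- drv$time >= config$outage[1] & drv$time < config$outage[2]
    nee[off] <- NA_real_
    qc[off] <- "missing"
  }
  series <- tibble::tibble(time = drv$time, year = drv$year, doy = drv$doy,
                           hod = drv$hod, nee = nee, rg = drv$rg,
                           tair = drv$tair, qc = qc)
  structure(list(series = series, truth = truth, lai = lai8, calendar = cal,
                 config = config), class = "tower_sim")
}

#' Configuration for the synthetic landscape
#'
#' A landscape of abstract pixels whose baseline LAI is drawn from a
#' two-component Gaussian mixture (scrub-like and tall-forest-like modes),
#' emulating the bimodal LAI distribution across mangrove stature classes.
#'
#' @param n_pixels Number of pixels (>= 1).
#' @param mixture_weights Two non-negative fractions summing to 1.
#' @param mode_means Two LAI mode means (m2 m-2, >= 0); defaults are the
#'   scrub and tall-forest site means.
#' @param mode_sds Two LAI mode SDs.
#' @param pixel_area Pixel area in m2 (default 250,000 = nominal 500 m cell).
#' @param seed Integer RNG seed.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(n_pixels, mixture_weights = c(0.5, 0.5),
                             mode_means = c(2.87, 5.55),
                             mode_sds = c(0.7, 0.7),
                             pixel_area = 250000, seed = 1L) {
  if (!is.numeric(n_pixels) || length(n_pixels) != 1 || n_pixels < 1 ||
      n_pixels != as.integer(n_pixels))
    stop("n_pixels must be a positive integer")
  if (length(mixture_weights) != 2 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-12)
    stop("mixture_weights must be two non-negative fractions summing to 1")
  if (length(mode_means) != 2 || any(mode_means < 0))
    stop("mode_means must be two non-negative LAI values")
  if (length(mode_sds) != 2 || any(mode_sds < 0))
    stop("mode_sds must be two non-negative LAI values")
  if (pixel_area <= 0) stop("pixel_area must be > 0")
  structure(list(n_pixels = as.integer(n_pixels),
                 mixture_weights = mixture_weights, mode_means = mode_means,
                 mode_sds = mode_sds, pixel_area = pixel_area,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Draw the per-pixel baseline LAI landscape
#'
#' @param config A [landscape_config()].
#' @return A tibble with `pixel_id`, `lai_baseline` (m2 m-2, truncated at 0
#'   by redrawing), and `area` (m2).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  n <- config$n_pixels
  comp <- sample.int(2L, n, replace = TRUE, prob = config$mixture_weights)
  lai <- stats::rnorm(n, config$mode_means[comp], config$mode_sds[comp])
  while (any(lai < 0)) {  # truncate at 0 by redrawing
    bad <- which(lai < 0)
    lai[bad] <- stats::rnorm(length(bad), config$mode_means[comp[bad]],
                             config$mode_sds[comp[bad]])
  }
  tibble::tibble(pixel_id = seq_len(n), lai_baseline = lai,
                 area = config$pixel_area)
}

#' Per-pixel per-period LAI trajectories for a simulated landscape
#'
#' Applies the tower's relative disturbance trajectory (same drop fraction,
#' recovery and overshoot timescales) to each pixel's baseline LAI, sampling
#' on the 8-day grid and compositing to the 24-day maximum, exactly as the
#' analysis pipeline treats tower LAI.
#'
#' @param pixels Tibble from [simulate_landscape()].
#' @param config A [sim_config()] supplying the disturbance trajectory.
#' @return A tibble with `pixel_id`, `year`, `period`, `lai`.
#' @export
simulate_pixel_lai <- function(pixels, config) {
  stopifnot(inherits(config, "sim_config"))
  t <- seq(0, config$n_years * 365L - 1L, by = 8L)
  rel <- lai_curve(t, 1, config$landfall_day, config$lai_drop_frac,
                   config$lai_recovery_days, config$lai_overshoot_frac,
                   config$lai_overshoot_days)
  per <- period_of_doy(t %% 365L + 1L)
  yr <- sim_years(config)[t %/% 365L + 1L]
  rel_comp <- tapply(rel, list(yr, per), max)  # periods complete by design
  grid <- expand.grid(year = as.integer(rownames(rel_comp)),
                      period = as.integer(colnames(rel_comp)))
  grid$rel <- as.vector(rel_comp)
  out <- tidyr::expand_grid(pixels[c("pixel_id", "lai_baseline")], grid)
  out$lai <- out$lai_baseline * out$rel
  dplyr::arrange(out[c("pixel_id", "year", "period", "lai")],
                 .data$pixel_id, .data$year, .data$period)
}

#' Analytically expected recovery debt of a simulated tower
#'
#' Evaluates the generating model directly (no noise, no missingness, no
#' fitting): half-hourly NEE from the per-period true parameters, the
#' reference as the mean over the 365 days before landfall, and the debt of
#' each post-landfall year as the sum of `(NEE_post - reference)` converted
#' to g C m-2. This is the independent oracle for the recovery-debt pipeline.
#'
#' @param config A [sim_config()]; its noise and missingness settings are
#'   ignored (evaluation is noise-free).
#' @param years Post-landfall years to integrate (default 1:4).
#' @return A tibble with `year_since_landfall`, `annual_debt`,
#'   `cumulative_debt` (g C m-2, positive = debt), and the reference NEE as
#'   attribute `reference_nee`.
#' @export
expected_debt <- function(config, years = 1:4) {
  stopifnot(inherits(config, "sim_config"))
  if (config$landfall_day < 365)
    stop("reference window extends before series start")
  if (config$landfall_day + max(years) * 365 > config$n_years * 365)
    stop("simulated span does not cover the requested post-landfall years")
  cfg0 <- config
  cfg0$noise_sd <- 0; cfg0$missing_frac <- 0
  cfg0$lai_noise_sd <- 0; cfg0$outage <- NULL
  sim <- simulate_tower(cfg0)
  ref <- reference_nee(sim$series, config$landfall_day)
  annual <- vapply(years, function(k)
    annual_debt(sim$series, ref, config$landfall_day, k), numeric(1))
  out <- tibble::tibble(year_since_landfall = years, annual_debt = annual,
                        cumulative_debt = cumsum(annual))
  attr(out, "reference_nee") <- ref
  out
}
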
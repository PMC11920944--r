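# End-to-end assembly: tower fits -> scaling-model training table ->
# per-pixel parameters -> landscape NEE reconstruction -> recovery debt.

period_seq_no <- function(year, period, year0, periods_per_year = 15L) {
  (year - year0) * periods_per_year + period
}

#' Time since disturbance per period, in 24-day periods
#'
#' Zero for periods up to and including the one containing landfall, then
#' counting upward, capped at `cap_years` of periods (the scaling model's
#' recovery horizon).
#'
#' @param calendar Period calendar from [build_periods()].
#' @param landfall_day Landfall as a day offset from Jan 1 of the calendar's
#'   first year.
#' @param cap_years Cap in years (default 4).
#' @return Integer vector aligned with the calendar rows.
#' @export
time_since_disturbance <- function(calendar, landfall_day, cap_years = 4) {
  year0 <- min(calendar$year)
  lf_year <- year0 + landfall_day %/% 365
  lf_period <- period_of_doy(landfall_day %% 365 + 1)
  lf_seq <- period_seq_no(lf_year, lf_period, year0)
  seq_no <- period_seq_no(calendar$year, calendar$period, year0)
  pmax(0L, pmin(as.integer(cap_years * 15), seq_no - lf_seq))
}

period_mean_tair <- function(drivers, calendar) {
  per <- period_of_doy(drivers$doy)
  key <- paste(drivers$year, per)
  cal_key <- paste(calendar$year, calendar$period)
  as.numeric(tapply(drivers$tair, factor(key, levels = cal_key), mean))
}

#' Assemble the scaling-model training table from tower fits
#'
#' Joins per-period response-curve fits with their covariates: composited
#' (and optionally gap-filled) period LAI, time since disturbance, stature
#' class from the pre-disturbance mean LAI, and period-mean air temperature.
#' Only periods whose relevant fit converged contribute.
#'
#' @param fits Output of [fit_period_curves()].
#' @param lai_series Period LAI from [composite_lai()] / [gapfill_linear()].
#' @param drivers Half-hourly driver tibble (`year`, `doy`, `tair`).
#' @param calendar Period calendar.
#' @param landfall_day Landfall day offset from Jan 1 of the first year.
#' @param site Optional site label.
#' @return Tibble with `site`, `year`, `period`, covariates (`lai`,
#'   `time_since`, `structure`, `tair`) and the fitted parameters (`qy`,
#'   `amax`, `reco`, `rb`, `e0`; non-converged fits as NA).
#' @export
scaling_training_data <- function(fits, lai_series, drivers, calendar,
                                  landfall_day, site = "site") {
  year0 <- min(calendar$year)
  offset <- (lai_series$year - year0) * 365 + lai_series$start_doy - 1
  lai_ref <- mean(lai_series$lai[offset < landfall_day], na.rm = TRUE)
  out <- dplyr::left_join(fits, lai_series[c("year", "period", "lai")],
                          by = c("year", "period"))
  out$time_since <- time_since_disturbance(calendar, landfall_day)
  out$structure <- classify_structure(lai_ref)
  out$tair <- period_mean_tair(drivers, calendar)
  lrc_bad <- !out$lrc_converged
  out$qy[lrc_bad] <- NA_real_
  out$amax[lrc_bad] <- NA_real_
  out$reco[lrc_bad] <- NA_real_
  trc_bad <- !out$trc_converged
  out$rb[trc_bad] <- NA_real_
  out$e0[trc_bad] <- NA_real_
  dplyr::bind_cols(tibble::tibble(site = rep(site, nrow(out))),
                   out[c("year", "period", "lai", "time_since", "structure",
                         "tair", "qy", "amax", "reco", "rb", "e0")])
}

#' Fit scaling models for all four parameters
#'
#' @param training Training table (typically several sites row-bound from
#'   [scaling_training_data()]).
#' @param link Link form passed to [fit_scaling()].
#' @return Named list of `scaling_model` objects
#'   (`reco_lrc`, `qy`, `amax`, `rb`).
#' @export
fit_scaling_models <- function(training, link = "identity-exp") {
  value_col <- c(reco_lrc = "reco", qy = "qy", amax = "amax", rb = "rb")
  models <- lapply(names(value_col), function(resp) {
    d <- training
    d$value <- d[[value_col[[resp]]]]
    fit_scaling(d, response = resp, link = link)
  })
  stats::setNames(models, names(value_col))
}

#' Predict per-pixel per-period parameters from scaling models
#'
#' @param models List from [fit_scaling_models()].
#' @param pixel_lai Tibble `pixel_id`, `year`, `period`, `lai`.
#' @param pixels Tibble `pixel_id`, `lai_baseline` (structure reference).
#' @param drivers Half-hourly drivers (for period-mean Tair).
#' @param calendar Period calendar.
#' @param landfall_day Landfall day offset.
#' @param e0 Temperature-sensitivity value used landscape-wide (E0 shows no
#'   disturbance response, so a single site-calibrated value is applied).
#' @param cap_years Time-since-disturbance cap (years).
#' @return Tibble `pixel_id, year, period, qy, amax, reco, rb, e0` with
#'   attribute `n_clipped` (total clipped predictions across responses).
#' @export
predict_pixel_params <- function(models, pixel_lai, pixels, drivers,
                                 calendar, landfall_day, e0,
                                 cap_years = 4) {
  cov <- tibble::tibble(year = calendar$year, period = calendar$period,
                        time_since = time_since_disturbance(calendar,
                                                            landfall_day,
                                                            cap_years),
                        tair = period_mean_tair(drivers, calendar))
  nd <- dplyr::left_join(pixel_lai, cov, by = c("year", "period"))
  nd <- dplyr::left_join(nd,
                         tibble::tibble(pixel_id = pixels$pixel_id,
                                        structure = classify_structure(
                                          pixels$lai_baseline)),
                         by = "pixel_id")
  preds <- lapply(models, predict_params, newdata = nd)
  out <- tibble::tibble(pixel_id = nd$pixel_id, year = nd$year,
                        period = nd$period,
                        qy = preds$qy, amax = preds$amax,
                        reco = preds$reco_lrc, rb = preds$rb,
                        e0 = rep(e0, nrow(nd)))
  attr(out, "n_clipped") <- sum(vapply(preds, attr, numeric(1),
                                       "n_clipped"))
  out
}

#' Per-pixel generating-truth parameters
#'
#' Evaluates a simulator parameter law at each pixel's per-period LAI --
#' the analytic counterpart of [predict_pixel_params()] used to validate
#' the landscape pipeline.
#'
#' @param param_law Function mapping LAI to `(qy, amax, reco, rb, e0)`.
#' @param pixel_lai Tibble `pixel_id`, `year`, `period`, `lai`.
#' @return Tibble `pixel_id, year, period, qy, amax, reco, rb, e0`.
#' @export
true_pixel_params <- function(param_law, pixel_lai) {
  dplyr::bind_cols(pixel_lai[c("pixel_id", "year", "period")],
                   param_law(pixel_lai$lai))
}

# Precompute the driver-side quantities shared by every pixel.
debt_driver_context <- function(drivers, landfall_day, years,
                                rg_threshold = 50) {
  year0 <- min(drivers$year)
  key <- (drivers$year - year0) * 15L + period_of_doy(drivers$doy)
  rel <- drivers$time - landfall_day
  ybin <- ifelse(rel >= 0, floor(rel / 365) + 1, NA_real_)
  ybin[!(ybin %in% years)] <- NA_real_
  list(year0 = year0, key = key,
       rg = drivers$rg, tair = drivers$tair,
       night = drivers$rg <= rg_threshold,
       pre = rel >= -365 & rel < 0,
       ybin = factor(ybin, levels = years),
       years = years)
}

# Debt for one pixel's parameter matrix under one variant.
pixel_debt_fast <- function(p, ctx, variant) {
  idx <- p$idx
  nee <- p$qy[idx] * p$amax[idx] * ctx$rg /
    (p$qy[idx] * ctx$rg + p$amax[idx]) + p$reco[idx]
  if (variant == "lrc_trc") {
    nt <- ctx$night
    nee[nt] <- p$rb[idx[nt]] *
      exp(p$e0[idx[nt]] * (1 / (TREF_C - T0_C) - 1 / (ctx$tair[nt] - T0_C)))
  }
  ref <- mean(nee[ctx$pre])
  sums <- tapply(nee - ref, ctx$ybin, sum)
  umol_sum_to_gc(as.numeric(sums))
}

#' Landscape recovery debt from per-pixel parameters
#'
#' Reconstructs half-hourly NEE for every pixel from its per-period
#' parameters and the shared drivers, takes each pixel's reference as the
#' mean modeled NEE over the year before landfall, and integrates annual and
#' cumulative recovery debt per pixel and for the landscape.
#'
#' @param pixel_params Tibble from [predict_pixel_params()] or
#'   [true_pixel_params()].
#' @param pixels Tibble `pixel_id`, `area` (m2).
#' @param drivers Half-hourly drivers covering at least one year before
#'   landfall through the last requested year.
#' @param landfall_day Landfall day offset from Jan 1 of the first driver
#'   year.
#' @param years Post-landfall years (default 1:4).
#' @param variants NEE reconstruction variants (default both).
#' @param rg_threshold Day/night split (W m-2).
#' @return A list:
#'   \describe{
#'     \item{per_pixel}{tibble `pixel_id, variant, year_since_landfall,
#'       annual_debt, cumulative_debt` (g C m-2)}
#'     \item{landscape}{tibble `variant, year_since_landfall, annual_mt_c,
#'       cumulative_mt_c, frac_pixels_negative` (cumulative-debt sign share
#'       per year)}
#'     \item{variant_summary}{per-year mean and SE of the landscape
#'       cumulative debt across variants}
#'   }
#' @export
landscape_recovery_debt <- function(pixel_params, pixels, drivers,
                                    landfall_day, years = 1:4,
                                    variants = c("lrc", "lrc_trc"),
                                    rg_threshold = 50) {
  ctx <- debt_driver_context(drivers, landfall_day, years, rg_threshold)
  split_params <- split(pixel_params, pixel_params$pixel_id)
  area <- stats::setNames(pixels$area, pixels$pixel_id)

  per_pixel <- list()
  for (variant in variants) {
    for (pid in names(split_params)) {
      pp <- split_params[[pid]]
      p <- list(qy = pp$qy, amax = pp$amax, reco = pp$reco,
                rb = pp$rb, e0 = pp$e0,
                idx = match(ctx$key,
                            (pp$year - ctx$year0) * 15L + pp$period))
      if (anyNA(p$idx))
        stop("pixel ", pid, ": parameters missing for some driver periods")
      ann <- pixel_debt_fast(p, ctx, variant)
      per_pixel[[paste(variant, pid)]] <- tibble::tibble(
        pixel_id = pp$pixel_id[1], variant = variant,
        year_since_landfall = years,
        annual_debt = ann, cumulative_debt = cumsum(ann))
    }
  }
  per_pixel <- dplyr::bind_rows(per_pixel)

  landscape <- dplyr::summarise(
    dplyr::group_by(per_pixel, .data$variant, .data$year_since_landfall),
    annual_mt_c = sum(.data$annual_debt *
                        area[as.character(.data$pixel_id)]) / 1e12,
    cumulative_mt_c = sum(.data$cumulative_debt *
                            area[as.character(.data$pixel_id)]) / 1e12,
    frac_pixels_negative = mean(.data$cumulative_debt < 0),
    .groups = "drop")

  variant_summary <- dplyr::summarise(
    dplyr::group_by(landscape, .data$year_since_landfall),
    dplyr::bind_cols(summarize_variants(.data$cumulative_mt_c)),
    .groups = "drop")

  list(per_pixel = per_pixel, landscape = landscape,
       variant_summary = variant_summary)
}

#' End-to-end landscape validation against generating truth
#'
#' Runs the full chain on a synthetic study: two noise-free calibration
#' towers (tall-forest and scrub baselines) struck by one hurricane, period
#' curve fits, scaling-model training across both sites, per-pixel parameter
#' prediction for a bimodal-LAI landscape, NEE reconstruction and recovery
#' debt -- then recomputes the same landscape debt directly from the
#' generating parameter law. The generating law is drawn from the
#' exponential scaling family itself ([scaling_family_param_law()]), so the
#' chain should reproduce the generating cumulative-debt trajectory almost
#' exactly; deviations reflect pipeline error, not model mismatch.
#'
#' The prescribed disturbance: 40% LAI drop at landfall, 90-day e-folding
#' refoliation, 10% regrowth overshoot (e-folding 500 days) -- a trajectory
#' giving a clear year-1 carbon debt followed by enhanced capture.
#'
#' @param n_pixels Landscape size (default 1000).
#' @param seed Base RNG seed.
#' @param link Scaling link form (default `"log"`, matching the generating
#'   family).
#' @param years Post-landfall years (default 1:4).
#' @return A list: `pipeline` and `truth` (each as
#'   [landscape_recovery_debt()] output), `models`, `e0`, `training`.
#' @export
validate_landscape_pipeline <- function(n_pixels = 1000, seed = 1L,
                                        link = "log", years = 1:4) {
  law <- scaling_family_param_law()
  tower_cfg <- function(baseline, s)
    sim_config(start_date = "2015-01-01", n_years = 7,
               landfall_date = "2017-09-10", lai_baseline = baseline,
               lai_drop_frac = 0.4, lai_recovery_days = 90,
               lai_overshoot_frac = 0.10, lai_overshoot_days = 500,
               param_law = law, noise_sd = 0, missing_frac = 0, seed = s)
  cfgs <- list(tall = tower_cfg(5.55, seed + 10L),
               scrub = tower_cfg(2.87, seed + 11L))
  train <- list(); e0s <- numeric()
  for (nm in names(cfgs)) {
    sim <- simulate_tower(cfgs[[nm]])
    fits <- fit_period_curves(filter_range(sim$series), sim$calendar)
    laip <- gapfill_linear(composite_lai(sim$lai, sim$calendar),
                           max_gap = 2)
    drv <- simulate_drivers(cfgs[[nm]])
    train[[nm]] <- scaling_training_data(fits, laip, drv, sim$calendar,
                                         cfgs[[nm]]$landfall_day, site = nm)
    e0s <- c(e0s, fits$e0[fits$trc_converged])
  }
  training <- dplyr::bind_rows(train)
  models <- fit_scaling_models(training, link = link)
  e0_hat <- mean(e0s)

  cfg <- cfgs$tall
  pixels <- simulate_landscape(landscape_config(n_pixels = n_pixels,
                                                seed = seed + 20L))
  plai <- simulate_pixel_lai(pixels, cfg)
  drv <- simulate_drivers(cfg)
  cal <- build_periods(sim_years(cfg))
  pp <- predict_pixel_params(models, plai, pixels, drv, cal,
                             cfg$landfall_day, e0 = e0_hat)
  pipeline <- landscape_recovery_debt(pp, pixels, drv, cfg$landfall_day,
                                      years = years)
  truth <- landscape_recovery_debt(true_pixel_params(law, plai), pixels,
                                   drv, cfg$landfall_day, years = years)
  list(pipeline = pipeline, truth = truth, models = models, e0 = e0_hat,
       training = training)
}
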
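# Light-response (Michaelis-Menten) and temperature-response (Lloyd-Taylor)
# curve fitting by bounded nonlinear least squares, per 24-day period.
#
# Sign conventions follow the NEE definition (negative = net uptake): QY and
# Amax are negative, Reco and rb positive. Bounds and starting values are the
# standard ones for this partitioning approach: QY -0.01 (-0.4..0), Amax
# start -10 (bounds -60..-0.01; the nominal start of magnitude 10 is clamped
# to the feasible sign), Reco 1 (0..100); rb 100 (0..1000), E0 starting at
# the mean nighttime NEE clamped into its bounds (50..400).

TREF_C <- 15
T0_C <- -46.02

#' Predict NEE from light-response parameters
#'
#' Michaelis-Menten light response:
#' `NEE = QY * Amax * Rg / (QY * Rg + Amax) + Reco`.
#' At `Rg = 0` this is `Reco`; it decreases monotonically with light towards
#' the asymptote `Amax + Reco`.
#'
#' @param rg Incoming shortwave radiation (W m-2, >= 0).
#' @param qy Quantum yield (umol/J, <= 0).
#' @param amax Light-saturated assimilation (umol CO2 m-2 s-1, < 0).
#' @param reco Ecosystem respiration intercept (umol CO2 m-2 s-1, >= 0).
#' @return NEE in umol CO2 m-2 s-1.
#' @export
#' @examples
#' predict_lrc(0, -0.1367, -32.14, 7.49)    # intercept: 7.49
#' predict_lrc(500, -0.14, -32.14, 7.49)    # about -14.5
predict_lrc <- function(rg, qy, amax, reco) {
  if (any(rg < 0, na.rm = TRUE)) stop("rg must be >= 0")
  denom <- qy * rg + amax
  if (any(denom == 0, na.rm = TRUE))
    stop("QY * Rg + Amax = 0: light response undefined")
  qy * amax * rg / denom + reco
}

#' Predict ecosystem respiration from temperature-response parameters
#'
#' Lloyd-Taylor respiration:
#' `Reco = rb * exp(E0 * (1 / (Tref - T0) - 1 / (Tair - T0)))`
#' with `Tref = 15` degC and `T0 = -46.02` degC held fixed. Equals `rb` at
#' `Tair = Tref` and increases strictly with temperature.
#'
#' @param tair Air temperature (degC, must exceed `T0`).
#' @param rb Base respiration at Tref (umol CO2 m-2 s-1, >= 0).
#' @param e0 Temperature-sensitivity parameter.
#' @param tref,t0 Fixed reference constants (degC).
#' @return Respiration in umol CO2 m-2 s-1.
#' @export
#' @examples
#' predict_trc(15, 3.22, 107.43)  # = rb at the reference temperature
predict_trc <- function(tair, rb, e0, tref = TREF_C, t0 = T0_C) {
  if (any(tair <= t0, na.rm = TRUE))
    stop("tair must be > T0 (", t0, " degC)")
  rb * exp(e0 * (1 / (tref - t0) - 1 / (tair - t0)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Projected Gauss-Newton polish: refines a converged solution to machine
# precision (numeric Jacobian; steps projected into the box). Keeps refits
# started from a previous optimum at that optimum.
polish_gn <- function(resid_fun, jac_fun, par, lower, upper,
                      max_iter = 10) {
  r <- resid_fun(par)
  sse <- sum(r^2)
  for (it in seq_len(max_iter)) {
    jac <- jac_fun(par)
    step <- tryCatch(qr.solve(jac, r), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    cand <- pmin(pmax(par - step, lower), upper)
    rc <- resid_fun(cand)
    if (!all(is.finite(rc)) || sum(rc^2) > sse * (1 + 1e-12)) break
    moved <- max(abs(cand - par) / pmax(abs(par), 1e-12))
    par <- cand; r <- rc; sse <- sum(r^2)
    if (moved < 1e-12) break
  }
  list(par = par, rmse = sqrt(mean(r^2)))
}

# Shared bounded NLS driver: nl2sol trust-region ("port") with box
# constraints, followed by a Gauss-Newton polish. Returns
# list(par, rmse, converged).
fit_bounded_nls <- function(formula, data, start, lower, upper,
                            max_iter = 1000, tol = 1e-10) {
  fit <- tryCatch(
    suppressWarnings(stats::nls(
      formula, data = data, start = as.list(start),
      lower = lower, upper = upper, algorithm = "port",
      control = stats::nls.control(maxiter = max_iter, tol = tol,
                                   warnOnly = TRUE, scaleOffset = 1)
    )),
    error = function(e) NULL
  )
  if (is.null(fit))
    return(list(par = stats::setNames(rep(NA_real_, length(start)),
                                      names(start)),
                rmse = NA_real_, converged = FALSE))
  par <- stats::coef(fit)
  rhs <- formula[[3L]]
  lhs <- eval(formula[[2L]], data)
  resid_fun <- function(p)
    lhs - eval(rhs, c(as.list(data), as.list(p)))
  dexpr <- stats::deriv(rhs, names(start))
  jac_fun <- function(p)
    -attr(eval(dexpr, c(as.list(data), as.list(p))), "gradient")
  pol <- polish_gn(resid_fun, jac_fun, par, lower, upper)
  list(par = pol$par, rmse = pol$rmse, converged = fit$convInfo$isConv)
}

lrc_refusal <- function(n_obs, coverage, status) {
  tibble::tibble(qy = NA_real_, amax = NA_real_, reco = NA_real_,
                 n_obs = n_obs, coverage = coverage, rmse = NA_real_,
                 converged = FALSE, status = status)
}

#' Fit a light response curve to daytime NEE
#'
#' Bounded least-squares fit of the Michaelis-Menten light response to
#' daytime half-hourly NEE. The fit is refused (distinct status, not an
#' error) when fewer than `min_coverage` of the expected daytime records are
#' available.
#'
#' @param nee Daytime NEE (umol CO2 m-2 s-1); NA pairs are dropped.
#' @param rg Daytime shortwave radiation (W m-2).
#' @param n_expected Number of daytime half-hours expected in the period
#'   (coverage denominator); defaults to `length(nee)`.
#' @param min_coverage Minimum coverage fraction to attempt a fit
#'   (default 0.4).
#' @param start,lower,upper Named start values and box bounds for
#'   `(qy, amax, reco)`.
#' @return One-row tibble: `qy, amax, reco, n_obs, coverage, rmse,
#'   converged, status` (`"ok"`, `"refused_coverage"`,
#'   `"refused_insufficient"` or `"failed"`).
#' @export
fit_lrc <- function(nee, rg, n_expected = length(nee), min_coverage = 0.4,
                    start = c(qy = -0.01, amax = -10, reco = 1),
                    lower = c(qy = -0.4, amax = -60, reco = 0),
                    upper = c(qy = 0, amax = -0.01, reco = 100)) {
  keep <- !is.na(nee) & !is.na(rg)
  nee <- nee[keep]; rg <- rg[keep]
  n_obs <- length(nee)
  coverage <- if (n_expected > 0) n_obs / n_expected else 0
  if (coverage < min_coverage)
    return(lrc_refusal(n_obs, coverage, "refused_coverage"))
  if (n_obs < 5 || length(unique(rg)) < 3)
    return(lrc_refusal(n_obs, coverage, "refused_insufficient"))
  # Deterministic multi-start: the nominal start, a data-driven start (low-
  # light regression for QY/Reco, high-light mean for the asymptote), and a
  # generic mid-magnitude start; the hyperbola's SSE surface has a local
  # trough at reco = 0 that can capture a single start.
  starts <- list(clamp(start, lower, upper))
  lo_rg <- rg <= stats::quantile(rg, 0.25)
  hi_rg <- rg >= stats::quantile(rg, 0.9)
  if (sum(lo_rg) >= 3 && sum(hi_rg) >= 3) {
    cf <- stats::coef(stats::lm.fit(cbind(1, rg[lo_rg]), nee[lo_rg]))
    reco0 <- cf[1]; qy0 <- cf[2]
    amax0 <- mean(nee[hi_rg]) - reco0
    starts <- c(starts, list(clamp(c(qy = qy0, amax = amax0, reco = reco0),
                                   lower * 0.999, upper))) # interior start
  }
  starts <- c(starts, list(clamp(c(qy = -0.1, amax = -30, reco = 5),
                                 lower, upper)))
  fits <- lapply(starts, function(s)
    fit_bounded_nls(nee ~ qy * amax * rg / (qy * rg + amax) + reco,
                    data = data.frame(nee = nee, rg = rg),
                    start = s, lower = lower, upper = upper))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  rmses <- vapply(fits, function(f)
    ifelse(is.na(f$rmse), Inf, f$rmse), numeric(1))
  res <- if (any(conv)) {
    cand <- which(conv & rmses <= min(rmses[conv]) * (1 + 1e-9))
    fits[[cand[1]]]  # ties go to the earliest (user-supplied) start
  } else fits[[which.min(rmses)]]
  tibble::tibble(qy = res$par[["qy"]], amax = res$par[["amax"]],
                 reco = res$par[["reco"]], n_obs = n_obs,
                 coverage = coverage, rmse = res$rmse,
                 converged = res$converged,
                 status = if (res$converged) "ok" else "failed")
}

trc_refusal <- function(n_obs, coverage, status) {
  tibble::tibble(rb = NA_real_, e0 = NA_real_, n_obs = n_obs,
                 coverage = coverage, rmse = NA_real_, converged = FALSE,
                 status = status)
}

#' Fit a temperature response curve to nighttime NEE
#'
#' Bounded least-squares fit of the Lloyd-Taylor respiration model to
#' nighttime half-hourly NEE. E0 starts at the mean nighttime NEE clamped
#' into its bounds. The fit is refused below the coverage threshold, or when
#' fewer than 3 distinct air temperatures make E0 unidentifiable.
#'
#' @param nee Nighttime NEE (umol CO2 m-2 s-1).
#' @param tair Nighttime air temperature (degC).
#' @param n_expected Expected number of nighttime half-hours (coverage
#'   denominator); defaults to `length(nee)`.
#' @param min_coverage Minimum coverage fraction (default 0.4).
#' @param start_rb Starting value for rb (default 100).
#' @param lower,upper Named box bounds for `(rb, e0)`.
#' @return One-row tibble: `rb, e0, n_obs, coverage, rmse, converged,
#'   status`.
#' @export
fit_trc <- function(nee, tair, n_expected = length(nee), min_coverage = 0.4,
                    start_rb = 100,
                    lower = c(rb = 0, e0 = 50),
                    upper = c(rb = 1000, e0 = 400)) {
  keep <- !is.na(nee) & !is.na(tair)
  nee <- nee[keep]; tair <- tair[keep]
  n_obs <- length(nee)
  coverage <- if (n_expected > 0) n_obs / n_expected else 0
  if (coverage < min_coverage)
    return(trc_refusal(n_obs, coverage, "refused_coverage"))
  if (n_obs < 5 || length(unique(tair)) < 3)
    return(trc_refusal(n_obs, coverage, "refused_unidentifiable"))
  start <- clamp(c(rb = start_rb, e0 = mean(nee)), lower, upper)
  res <- fit_bounded_nls(
    nee ~ rb * exp(e0 * (1 / (TREF_C - T0_C) - 1 / (tair - T0_C))),
    data = data.frame(nee = nee, tair = tair),
    start = start, lower = lower, upper = upper)
  tibble::tibble(rb = res$par[["rb"]], e0 = res$par[["e0"]], n_obs = n_obs,
                 coverage = coverage, rmse = res$rmse,
                 converged = res$converged,
                 status = if (res$converged) "ok" else "failed")
}

#' Fit light and temperature response curves for every 24-day period
#'
#' Applies the range filter mask (records must pass QC), splits day/night at
#' the radiation threshold, computes mask-specific coverage per period, and
#' fits the LRC to daytime and the TRC to nighttime records of each period
#' that meets the 40% availability rule.
#'
#' @param series Full-grid flux tibble (`time, year, doy, nee, rg, tair,
#'   qc`), typically after [filter_range()].
#' @param calendar Period calendar from [build_periods()].
#' @param rg_threshold Day/night split (W m-2, default 50).
#' @param min_coverage Minimum per-mask coverage (default 0.4).
#' @param ... Passed on to [fit_lrc()] and [fit_trc()] (e.g. bounds).
#' @return A tibble with one row per period: `year`, `period`, LRC columns
#'   (`qy, amax, reco, lrc_*`) and TRC columns (`rb, e0, trc_*`).
#' @export
fit_period_curves <- function(series, calendar, rg_threshold = 50,
                              min_coverage = 0.4, ...) {
  check_flux(series, c("year", "doy", "nee", "rg", "tair", "qc"))
  masks <- split_daynight(series, rg_threshold)
  ok <- flux_ok(series)
  per <- period_of_doy(series$doy)
  key <- paste(series$year, per)
  cov_day <- period_coverage(series, calendar, masks$day)
  cov_night <- period_coverage(series, calendar, masks$night)

  rows <- lapply(seq_len(nrow(calendar)), function(i) {
    sel <- key == paste(calendar$year[i], calendar$period[i])
    d <- sel & masks$day & ok
    n <- sel & masks$night & ok
    lrc <- fit_lrc(series$nee[d], series$rg[d],
                   n_expected = cov_day$n_expected[i],
                   min_coverage = min_coverage, ...)
    trc <- fit_trc(series$nee[n], series$tair[n],
                   n_expected = cov_night$n_expected[i],
                   min_coverage = min_coverage)
    names(lrc)[4:8] <- paste0("lrc_", names(lrc)[4:8])
    names(trc)[3:7] <- paste0("trc_", names(trc)[3:7])
    dplyr::bind_cols(calendar[i, c("year", "period")], lrc, trc)
  })
  dplyr::bind_rows(rows)
}

#' Reshape per-period fits to a tidy long parameter table
#'
#' @param fits Output of [fit_period_curves()].
#' @param site Optional site label column value.
#' @return Tidy tibble: `site` (if given), `year`, `period`, `variable`
#'   (one of `qy, amax, reco_lrc, rb, e0`), `estimate`, `converged`.
#' @export
tidy_params <- function(fits, site = NULL) {
  long <- tidyr::pivot_longer(
    fits[c("year", "period", "qy", "amax", "reco", "rb", "e0",
           "lrc_converged", "trc_converged")],
    cols = c("qy", "amax", "reco", "rb", "e0"),
    names_to = "variable", values_to = "estimate")
  long$variable[long$variable == "reco"] <- "reco_lrc"
  long$converged <- ifelse(long$variable %in% c("rb", "e0"),
                           long$trc_converged, long$lrc_converged)
  long <- long[c("year", "period", "variable", "estimate", "converged")]
  if (!is.null(site)) long <- dplyr::bind_cols(tibble::tibble(site = site),
                                               long)
  long
}
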
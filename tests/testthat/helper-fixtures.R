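# Shared fixtures: small noise-free and noisy simulator configurations.

quiet_config <- function(n_years = 3, landfall_date = "2016-09-10",
                         seed = 1L, ...) {
  sim_config(start_date = "2015-01-01", n_years = n_years,
             landfall_date = landfall_date, noise_sd = 0, missing_frac = 0,
             seed = seed, ...)
}

rel_err <- function(est, truth) max(abs(est - truth) / abs(truth))

# Minimal full-grid one-year flux series with constant values.
flat_series <- function(nee = -5, n_days = 365, year = 2015) {
  n <- n_days * 48
  day <- rep(0:(n_days - 1), each = 48)
  hod <- rep(seq(0, 23.5, by = 0.5), times = n_days)
  tibble::tibble(time = day + hod / 24, year = year, doy = day %% 365 + 1,
                 hod = hod, nee = rep(nee, n), rg = 0, tair = 25, qc = "ok")
}
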
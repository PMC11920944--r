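test_that("configuration errors are caught", {
  expect_error(sim_config(n_years = 0), "n_years")
  expect_error(sim_config(lai_drop_frac = 1.5), "lai_drop_frac")
  expect_error(sim_config(lai_baseline = 0), "lai_baseline")
  expect_error(sim_config(missing_frac = 1), "missing_frac")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_years = 1, landfall_date = "2019-01-01"),
               "within the simulated span")
})

test_that("identical seeds give identical simulations", {
  cfg <- sim_config(n_years = 1, landfall_date = "2015-07-01",
                    noise_sd = 2, missing_frac = 0.3, lai_noise_sd = 0.2,
                    seed = 7L)
  a <- simulate_tower(cfg)
  b <- simulate_tower(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_lai(cfg), simulate_lai(cfg))
})

test_that("drivers have the right grid, zero midnight radiation, and mean", {
  cfg <- quiet_config(n_years = 1, landfall_date = "2015-07-01")
  drv <- simulate_drivers(cfg)
  expect_equal(nrow(drv), 365 * 48)
  expect_true(all(drv$rg >= 0))
  expect_true(all(drv$rg[drv$hod == 0] == 0))
  # oracle: the discrete seasonal/diurnal cosines average out exactly
  expect_lt(abs(mean(drv$tair) - cfg$tair_mean), 0.1)
})

test_that("the LAI trajectory follows the drop-and-recovery law", {
  # landfall day offset 624 lies on the 8-day sampling grid
  base <- quiet_config(n_years = 3, landfall_date = "2016-09-17",
                       lai_baseline = 6)
  no_drop <- simulate_lai(quiet_config(n_years = 3,
                                       landfall_date = "2016-09-17",
                                       lai_baseline = 6,
                                       lai_drop_frac = 0))
  expect_true(all(no_drop$lai == 6))

  cfg <- quiet_config(n_years = 3, landfall_date = "2016-09-17",
                      lai_baseline = 6, lai_drop_frac = 0.5,
                      lai_recovery_days = 104)
  lai <- simulate_lai(cfg)
  expect_equal(lai$lai[lai$time < cfg$landfall_day],
               rep(6, sum(lai$time < cfg$landfall_day)))
  expect_equal(lai$lai[lai$time == cfg$landfall_day], 3.0)
  # one e-folding time after landfall: 6 - 3 * exp(-1)
  expect_equal(lai$lai[lai$time == cfg$landfall_day + 104], 4.896362,
               tolerance = 1e-6)
})

test_that("noise-free tower NEE is the generative model exactly", {
  cfg <- quiet_config(n_years = 1, landfall_date = "2015-09-10")
  sim <- simulate_tower(cfg)
  s <- sim$series
  idx <- match(s$year * 100 + period_of_doy(s$doy),
               sim$truth$year * 100 + sim$truth$period)
  day <- s$rg > cfg$rg_threshold
  expect_equal(s$nee[day],
               predict_lrc(s$rg[day], sim$truth$qy[idx][day],
                           sim$truth$amax[idx][day],
                           sim$truth$reco[idx][day]))
  expect_equal(s$nee[!day],
               predict_trc(s$tair[!day], sim$truth$rb[idx][!day],
                           sim$truth$e0[idx][!day]))
  # Rg = 0 records are pure temperature response
  z <- s$rg == 0
  expect_equal(s$nee[z], predict_trc(s$tair[z], sim$truth$rb[idx][z],
                                     sim$truth$e0[idx][z]))
})

test_that("injected NEE noise is recovered from residuals", {
  cfg <- sim_config(n_years = 1, landfall_date = "2015-09-10",
                    noise_sd = 2, missing_frac = 0, seed = 7L)
  sim <- simulate_tower(cfg)
  cfg0 <- sim_config(n_years = 1, landfall_date = "2015-09-10",
                     noise_sd = 0, missing_frac = 0, seed = 7L)
  clean <- simulate_tower(cfg0)
  resid <- sim$series$nee - clean$series$nee
  expect_gt(length(resid), 10000)
  expect_lt(abs(stats::sd(resid) - 2), 0.1)
})

test_that("missingness and outages blank NEE but keep drivers", {
  cfg <- sim_config(n_years = 1, landfall_date = "2015-09-10",
                    noise_sd = 0, missing_frac = 0.25,
                    outage = c(200, 230), seed = 3L)
  sim <- simulate_tower(cfg)
  s <- sim$series
  expect_equal(nrow(s), 365 * 48)  # full grid retained
  off <- s$time >= 200 & s$time < 230
  expect_true(all(is.na(s$nee[off])))
  expect_true(all(s$qc[off] == "missing"))
  expect_false(anyNA(s$rg))
  frac <- mean(is.na(s$nee[!off]))
  expect_lt(abs(frac - 0.25), 0.02)
})

test_that("landscape LAI follows the configured mixture", {
  one <- simulate_landscape(landscape_config(50, mixture_weights = c(1, 0),
                                             mode_means = c(3, 5.5),
                                             mode_sds = c(0, 0.7)))
  expect_true(all(one$lai_baseline == 3))

  lc <- landscape_config(10000, mode_means = c(2.9, 5.5), seed = 3L)
  px <- simulate_landscape(lc)
  # oracle: mixture mean 0.5*2.9 + 0.5*5.5 = 4.2; var = wtd second moments
  mix_var <- 0.5 * (0.7^2 + 2.9^2) + 0.5 * (0.7^2 + 5.5^2) - 4.2^2
  expect_lt(abs(mean(px$lai_baseline) - 4.2),
            3 * sqrt(mix_var / 10000))
  expect_true(all(px$lai_baseline >= 0))
})

test_that("landscape configuration errors are caught", {
  expect_error(landscape_config(0), "n_pixels")
  expect_error(landscape_config(10, mode_means = c(-1, 5)), "mode_means")
  expect_error(landscape_config(10, mixture_weights = c(0.6, 0.6)),
               "summing to 1")
  expect_error(landscape_config(10, pixel_area = 0), "pixel_area")
})

test_that("zero disturbance means zero expected debt", {
  cfg <- quiet_config(n_years = 6, lai_drop_frac = 0)
  ed <- expected_debt(cfg)
  expect_true(all(abs(ed$annual_debt) < 1e-9))
  expect_true(all(abs(ed$cumulative_debt) < 1e-9))
})

test_that("expected debt demands a complete pre-landfall year", {
  expect_error(expected_debt(quiet_config(n_years = 6,
                                          landfall_date = "2015-06-01")),
               "before series start")
})
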
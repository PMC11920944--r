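tall <- list(qy = -0.1367, amax = -32.14, reco = 7.49,
             rb = 3.22, e0 = 107.43)
scrub <- list(qy = -0.0738, amax = -9.97, reco = 1.76,
              rb = 0.96, e0 = 118.36)

test_that("light response curve has the right intercept and asymptote", {
  expect_equal(predict_lrc(0, tall$qy, tall$amax, tall$reco), 7.49)
  expect_equal(predict_lrc(1e9, tall$qy, tall$amax, tall$reco),
               tall$amax + tall$reco, tolerance = 1e-4)
  # hand-evaluated midpoint
  expect_equal(predict_lrc(500, -0.14, -32.14, 7.49), -14.5366,
               tolerance = 1e-4)
  expect_error(predict_lrc(-1, tall$qy, tall$amax, tall$reco), ">= 0")
})

test_that("light response is monotone non-increasing in radiation", {
  set.seed(8)
  rg <- seq(0, 1200, by = 10)
  for (i in 1:40) {
    qy <- stats::runif(1, -0.4, -0.001)
    amax <- stats::runif(1, -60, -0.01)
    reco <- stats::runif(1, 0, 100)
    expect_true(all(diff(predict_lrc(rg, qy, amax, reco)) <= 1e-12))
  }
})

test_that("temperature response passes through rb at Tref and increases", {
  expect_equal(predict_trc(15, tall$rb, tall$e0), 3.22)
  expect_equal(predict_trc(25, tall$rb, tall$e0), 4.126, tolerance = 1e-3)
  expect_equal(predict_trc(15, 5, 50), 5)  # exponent zero regardless of E0
  t <- seq(0, 35, by = 0.5)
  expect_true(all(diff(predict_trc(t, tall$rb, tall$e0)) > 0))
  expect_error(predict_trc(-50, tall$rb, tall$e0), "T0")
})

test_that("noiseless light-response data refits to the generating values", {
  set.seed(2)
  rg <- stats::runif(500, 51, 1000)
  nee <- predict_lrc(rg, scrub$qy, scrub$amax, scrub$reco)
  fit <- fit_lrc(nee, rg)
  expect_equal(fit$status, "ok")
  expect_lt(rel_err(c(fit$qy, fit$amax, fit$reco),
                    c(scrub$qy, scrub$amax, scrub$reco)), 1e-4)
  expect_lt(fit$rmse, 1e-6 * stats::sd(nee))
})

test_that("noiseless temperature-response data refits exactly", {
  set.seed(3)
  tair <- stats::runif(400, 15, 32)
  nee <- predict_trc(tair, scrub$rb, scrub$e0)
  fit <- fit_trc(nee, tair)
  expect_equal(fit$status, "ok")
  expect_lt(rel_err(c(fit$rb, fit$e0), c(scrub$rb, scrub$e0)), 1e-4)
})

test_that("refitting from the optimum is stable", {
  set.seed(4)
  rg <- stats::runif(300, 51, 900)
  nee <- predict_lrc(rg, tall$qy, tall$amax, tall$reco) +
    stats::rnorm(300, 0, 2)
  f1 <- fit_lrc(nee, rg)
  f2 <- fit_lrc(nee, rg, start = c(qy = f1$qy, amax = f1$amax,
                                   reco = f1$reco))
  expect_lt(max(abs(c(f2$qy - f1$qy, f2$amax - f1$amax,
                      f2$reco - f1$reco))), 1e-8)
})

test_that("fits below 40% coverage are refused, not errors", {
  set.seed(5)
  rg <- stats::runif(39, 51, 900)
  nee <- predict_lrc(rg, tall$qy, tall$amax, tall$reco)
  ref <- fit_lrc(nee, rg, n_expected = 100)
  expect_equal(ref$status, "refused_coverage")
  expect_false(ref$converged)
  expect_true(is.na(ref$qy))

  tr <- fit_trc(predict_trc(stats::runif(39, 15, 30), 1, 100),
                stats::runif(39, 15, 30), n_expected = 100)
  expect_equal(tr$status, "refused_coverage")
})

test_that("isothermal nighttime data makes E0 unidentifiable", {
  nee <- rep(2.5, 50)
  tair <- rep(22, 50)
  fit <- fit_trc(nee, tair)
  expect_equal(fit$status, "refused_unidentifiable")
})

test_that("successful fits respect the sign conventions", {
  set.seed(6)
  for (i in 1:5) {
    rg <- stats::runif(400, 51, 1000)
    nee <- predict_lrc(rg, tall$qy, tall$amax, tall$reco) +
      stats::rnorm(400, 0, 3)
    f <- fit_lrc(nee, rg)
    expect_lte(f$qy, 0)
    expect_lt(f$amax, 0)
    expect_gte(f$reco, 0)
    tair <- stats::runif(300, 12, 32)
    rn <- predict_trc(tair, tall$rb, tall$e0) + stats::rnorm(300, 0, 1)
    ft <- fit_trc(rn, tair)
    expect_gte(ft$rb, 0)
  }
})

test_that("per-period fitting recovers truth and refuses outage periods", {
  cfg <- quiet_config(n_years = 1, landfall_date = "2015-09-10",
                      outage = c(26, 46))  # blanks most of period 2
  sim <- simulate_tower(cfg)
  fits <- fit_period_curves(filter_range(sim$series), sim$calendar)
  expect_equal(fits$lrc_status[fits$period == 2], "refused_coverage")
  ok <- fits$lrc_status == "ok"
  m <- merge(fits[ok, ], sim$truth, by = c("year", "period"),
             suffixes = c("", ".true"))
  expect_lt(rel_err(m$qy, m$qy.true), 1e-4)
  expect_lt(rel_err(m$amax, m$amax.true), 1e-4)
  expect_lt(rel_err(m$reco, m$reco.true), 1e-4)
  okt <- fits$trc_status == "ok"
  mt <- merge(fits[okt, ], sim$truth, by = c("year", "period"),
              suffixes = c("", ".true"))
  expect_lt(rel_err(mt$rb, mt$rb.true), 1e-4)
  expect_lt(rel_err(mt$e0, mt$e0.true), 1e-4)
})

test_that("tidy parameter tables are long and labeled", {
  cfg <- quiet_config(n_years = 1, landfall_date = "2015-09-10")
  sim <- simulate_tower(cfg)
  fits <- fit_period_curves(filter_range(sim$series), sim$calendar)
  tidy <- tidy_params(fits, site = "tall")
  expect_setequal(unique(tidy$variable),
                  c("qy", "amax", "reco_lrc", "rb", "e0"))
  expect_equal(nrow(tidy), nrow(fits) * 5)
  expect_true(all(tidy$site == "tall"))
})
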
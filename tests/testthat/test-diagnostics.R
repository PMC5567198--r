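test_that("residual validation behaves on exact normal quantiles", {
  z <- qnorm((1:200 - 0.5) / 200)
  dg <- validate_residuals(z)
  expect_gt(dg$ks_pvalue, 0.99)
  expect_true(dg$box_pierce_pvalue >= 0 && dg$box_pierce_pvalue <= 1)
  expect_error(validate_residuals(rep(1, 50)), "constant")
  expect_error(validate_residuals(rnorm(10)), "at least 30")
})

test_that("autocorrelated residuals are caught by the Box-Pierce test", {
  set.seed(606)
  caught <- replicate(40, {
    z <- as.numeric(stats::arima.sim(list(ar = 0.5), 600))
    validate_residuals(z)$box_pierce_pvalue < 0.01
  })
  expect_gte(mean(caught), 0.95)
})

test_that("diagnostic p-values are calibrated on the null", {
  set.seed(707)
  ps <- t(replicate(100, unlist(
    validate_residuals(rnorm(300))[c("ks_pvalue", "box_pierce_pvalue")])))
  expect_gt(stats::ks.test(ps[, 1], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(ps[, 2], "punif")$p.value, 0.01)
})

test_that("daily aggregation adds session means and variances", {
  m <- tibble::tibble(session = 1:2, hours = c(0, 10), label = c("morning", "evening"),
                      mean_measured = c(18, 15), var_total = c(0.9, 0.7))
  day <- aggregate_daily(m)
  expect_equal(day$mean, 33)
  expect_equal(day$variance, 1.6)
  expect_equal(day$n_sessions, 2L)
})

test_that("daily aggregation conserves the lactation total", {
  m <- session_moments(ref_schedule(61), ref_params(), ref_var_params())
  day <- aggregate_daily(m)
  expect_equal(sum(day$mean), sum(m$mean_measured), tolerance = 1e-12)
  expect_equal(sum(day$variance), sum(m$var_total), tolerance = 1e-12)
  # odd session count: one day holds a single session
  expect_true(any(day$n_sessions == 1))
})

test_that("fit summaries report correlation, totals and the smoothed peak", {
  obs <- c(10, 12, 14, 13)
  s <- fit_summaries(obs, obs)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$total_observed_kg, s$total_fitted_kg)
  set.seed(808)
  s0 <- fit_summaries(rnorm(500), rnorm(500))
  expect_lt(abs(s0$pearson_r), 0.15)
  expect_error(fit_summaries(1:3, 1:4), "same length")
  daily <- tibble::tibble(day = 1:100,
                          mean = wood_curve(1:100, 20, 0.2, 0.01))
  s1 <- fit_summaries(obs, obs, daily = daily)
  expect_equal(s1$peak_day, 20, tolerance = 3)
})

test_that("variance-explained ratio is about one on well-specified data", {
  set.seed(909)
  ratios <- vapply(1:6, function(r) {
    d <- simulate_lactation(sim_config(n_days = 120, params = flat_params(),
                                       seed = 4000 + r))
    m <- session_moments(dplyr::select(d, -"yield"), flat_params(),
                         ref_var_params())
    fit_summaries(d$yield, m$mean_measured, m$var_total)$variance_explained_ratio
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})
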
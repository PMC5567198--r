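test_that("simulation is reproducible under a fixed seed", {
  d1 <- simulate_lactation(sim_config(n_days = 30, seed = 99))
  d2 <- simulate_lactation(sim_config(n_days = 30, seed = 99))
  expect_identical(d1, d2)
  d3 <- simulate_lactation(sim_config(n_days = 30, seed = 100))
  expect_false(identical(d1$yield, d3$yield))
})

test_that("schedules have two sessions per day at the nominal rhythm", {
  s <- simulate_schedule(sim_config(n_days = 305, seed = 1))
  expect_equal(nrow(s), 610L)
  s0 <- simulate_schedule(sim_config(n_days = 10, jitter_intervals = FALSE))
  gaps <- diff(s0$hours)
  expect_equal(gaps, rep(c(10, 14), length.out = 19))
  set.seed(2)
  big <- simulate_schedule(sim_config(n_days = 2000, seed = 3))
  morning_gaps <- diff(big$hours)[big$label[-1] == "morning"]
  expect_equal(mean(morning_gaps), 14, tolerance = 0.05)
  expect_equal(var(morning_gaps), 0.25, tolerance = 0.05)
})

test_that("with all noise off the simulator reproduces the deterministic series", {
  cfg <- sim_config(n_days = 40, production_noise = FALSE,
                    retention_noise = FALSE, measurement_noise = FALSE,
                    jitter_intervals = FALSE)
  d <- simulate_lactation(cfg)
  det <- extraction_series(dplyr::select(d, -"yield"), ref_params())
  expect_equal(d$yield, det$y_extracted, tolerance = 1e-12)
  lat <- attr(d, "latent")
  expect_equal(lat$y_produced, det$y_produced, tolerance = 1e-12)
  expect_equal(lat$y_residual, det$y_residual, tolerance = 1e-12)
})

test_that("replicate draws match the propagated moments", {
  set.seed(515)
  cfg <- sim_config(n_days = 4, jitter_intervals = FALSE)
  cfg$seed <- NULL
  n_rep <- 4000
  ys <- matrix(0, n_rep, 8)
  for (r in seq_len(n_rep)) ys[r, ] <- simulate_lactation(cfg)$yield
  m <- session_moments(nominal_schedule(8), ref_params(), ref_var_params())
  se_mean <- sqrt(m$var_total / n_rep)
  expect_true(all(abs(colMeans(ys) - m$mean_measured) < 4 * se_mean))
  v <- apply(ys, 2, var)
  se_var <- m$var_total * sqrt(2 / (n_rep - 1))
  expect_true(all(abs(v - m$var_total) < 4 * se_var))
})

test_that("simulated lactation totals sit at the reference scale", {
  tot <- vapply(1:3, function(s)
    sum(simulate_lactation(sim_config(seed = s))$yield), numeric(1))
  m <- session_moments(nominal_schedule(610), ref_params(), ref_var_params())
  expect_equal(mean(tot), sum(m$mean_measured), tolerance = 0.02)
})

test_that("the recovery harness reports bias, rmse and coverage per term", {
  cfg <- sim_config(n_days = 60, params = flat_params())
  rec <- recovery_harness(cfg, n_replicates = 3, seed = 7,
                          workflow = "stage1")
  expect_setequal(rec$summary$term,
                  c("delta", "lambda_A", "lambda_R", "pi", "phi", "pl_max"))
  expect_true(all(rec$summary$rmse >= 0))
  expect_true(all(rec$summary$coverage >= 0 & rec$summary$coverage <= 1))
  expect_equal(nrow(rec$replicates), 3 * 6)
})
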
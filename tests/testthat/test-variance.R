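test_that("variance components sum to the total at every session", {
  m <- session_moments(ref_schedule(60), ref_params(), ref_var_params())
  expect_lt(max(abs(m$var_total -
                      (m$v_mes + m$v_ret + m$v_rec + m$v_pro + m$v_alv))),
            1e-10 * max(m$var_total))
  expect_true(all(m[c("v_mes", "v_ret", "v_rec", "v_pro", "v_alv")] >= 0))
  m2 <- session_moments(ref_schedule(60), ref_params(), ref_var_params(),
                        interval_uncertainty = TRUE)
  expect_lt(max(abs(m2$var_total -
                      (m2$v_mes + m2$v_ret + m2$v_rec + m2$v_pro + m2$v_alv +
                         m2$v_tim))), 1e-10 * max(m2$var_total))
})

test_that("with no retention, dispersion or secretion segments only measurement error survives", {
  p <- milk_params(pi = 0, pi_overrides = NULL, pl = 1.41)
  vp <- var_params(phi = 0)
  m <- session_moments(ref_schedule(12), p, vp)
  expect_equal(m$var_total, m$mean_measured^2 * vp$cv_measurement^2,
               tolerance = 1e-12)
  expect_true(all(m$v_ret == 0))
  expect_true(all(m$v_rec == 0))
  expect_true(all(m$v_pro == 0))
  expect_true(all(m$v_alv == 0))
})

test_that("production variance terms vanish in their degenerate limits", {
  pm <- production_moments(100, 114, pl_interval = 1.41, pl_max = 1.41,
                           lambda_A = 64e-4, lambda_R = 45e-6, phi = 0.54)
  expect_identical(pm$v_pl, 0)            # beta = 1
  pm0 <- production_moments(100, 114, pl_interval = 1.2, pl_max = 1.41,
                            lambda_A = 64e-4, lambda_R = 45e-6, phi = 0)
  expect_identical(pm0$v_pa, 0)           # phi = 0
})

test_that("the activated-alveoli variance term matches an independent scalar evaluation", {
  la <- 64e-4; lr <- 45e-6; phi <- 0.54
  pl_max <- 1.41; pl_int <- 1.32
  t0 <- 100; t1 <- 114
  # term-by-term re-implementation from first principles
  w_r <- (1 / lr) * (exp(-lr * t0) - exp(-lr * t1))
  w_a <- (1 / la) * (exp(-la * t0) - exp(-la * t1))
  mna <- (la / (la - lr)) * (w_r - w_a) / (t1 - t0)
  beta <- pl_int / pl_max
  v_pa_ref <- (pl_max * beta)^2 * (t1 - t0) * phi * mna * (1 - mna)
  v_pl_ref <- pl_max * (t1 - t0) * mna * beta * (1 - beta)
  pm <- production_moments(t0, t1, pl_int, pl_max, la, lr, phi)
  expect_equal(pm$v_pa, v_pa_ref, tolerance = 1e-12)
  expect_equal(pm$v_pl, v_pl_ref, tolerance = 1e-12)
  expect_equal(pm$mean, pl_int * (t1 - t0) * mna, tolerance = 1e-12)
})

test_that("propagated moments match a Monte-Carlo oracle over a 20-session chain", {
  set.seed(421)
  sched <- ref_schedule(20)
  params <- ref_params()       # includes beta segments and extreme sessions
  vp <- ref_var_params()
  m <- session_moments(sched, params, vp)
  mc <- mc_chain_moments(sched, params, vp, n_rep = 1e5)
  se_mean <- sqrt(mc$var / 1e5)
  se_var <- mc$var * sqrt(2 / (1e5 - 1))
  expect_true(all(abs(m$mean_measured - mc$mean) < 3 * se_mean))
  expect_true(all(abs(m$var_total - mc$var) < 3 * se_var))
})

test_that("zero retention kills the retention and carryover components everywhere", {
  p <- milk_params(pi = 0, pi_overrides = NULL)
  m <- session_moments(ref_schedule(30), p, ref_var_params())
  expect_true(all(m$v_ret == 0))
  expect_true(all(m$v_rec == 0))
})

test_that("interval-duration variance behaves like a delta-method term", {
  p <- flat_params()
  vp <- ref_var_params()
  # linear in var_T, zero when var_T = 0
  expect_identical(timing_variance(200, "morning", p, var_params(var_T = 0)), 0)
  v1 <- timing_variance(200, "morning", p, var_params(var_T = 0.25))
  v2 <- timing_variance(200, "morning", p, var_params(var_T = 0.5))
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # numeric-differentiation oracle: d Y_E / d(interval length)
  h <- 1e-4
  dY <- (secreted_between_sessions(200, 214 + h, 1.41, p$lambda_A, p$lambda_R) -
         secreted_between_sessions(200, 214 - h, 1.41, p$lambda_A, p$lambda_R)) /
        (2 * h)
  ref <- (1 - p$pi)^2 * dY^2 * vp$var_T
  expect_equal(v1, ref, tolerance = 0.01)
  # vanishing extraction (pi -> 1) kills the term
  p99 <- milk_params(pi = 0.999, pi_overrides = NULL)
  expect_lt(timing_variance(200, "morning", p99, vp) / v1, 1e-4)
})

test_that("adding interval uncertainty strictly increases total variance", {
  m0 <- session_moments(ref_schedule(20), ref_params(), ref_var_params())
  m1 <- session_moments(ref_schedule(20), ref_params(), ref_var_params(),
                        interval_uncertainty = TRUE)
  expect_true(all(m1$var_total > m0$var_total))
})

test_that("variance shares normalise per session and over the lactation", {
  m <- session_moments(ref_schedule(50), ref_params(), ref_var_params())
  sh <- variance_shares(m)
  share_cols <- grep("^share_", names(sh$per_session), value = TRUE)
  expect_equal(rowSums(sh$per_session[share_cols]), rep(1, 50),
               tolerance = 1e-12)
  expect_equal(sum(sh$overall), 1, tolerance = 1e-12)
  # single surviving component takes share 1
  p <- milk_params(pi = 0, pi_overrides = NULL, pl = 1.41)
  sh1 <- variance_shares(session_moments(ref_schedule(6), p,
                                         var_params(phi = 0)))
  expect_equal(sh1$overall$share_mes, 1, tolerance = 1e-12)
  expect_error(variance_shares(m[0, ]), "empty")
})
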
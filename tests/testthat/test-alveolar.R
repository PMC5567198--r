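test_that("alveolar proportions start at (1, 0, 0) and always sum to one", {
  s0 <- alveolar_state(0, lambda_A = 64e-4, lambda_R = 45e-6)
  expect_equal(unlist(s0[c("n_inactive", "n_active", "n_retired")]),
               c(n_inactive = 1, n_active = 0, n_retired = 0))
  tt <- c(0, 1, 10, 100, 1000, 7320)
  for (la in c(1e-3, 64e-4, 0.05)) {
    for (lr in c(0, 45e-6, 1e-3, la)) {
      s <- alveolar_state(tt, la, lr)
      expect_lt(max(abs(s$n_inactive + s$n_active + s$n_retired - 1)), 1e-12)
      expect_true(all(diff(s$n_inactive) <= 0))
      expect_true(all(diff(s$n_retired) >= -1e-14))
      expect_true(all(s$n_active >= 0 & s$n_active <= 1))
    }
  }
})

test_that("with no inactivation the active fraction is 1 - exp(-lambda_A t)", {
  s <- alveolar_state(100, lambda_A = 0.0064, lambda_R = 0)
  expect_equal(s$n_active, 1 - exp(-0.64), tolerance = 1e-12)
})

test_that("closed form matches a numeric ODE oracle, including near-degenerate rates", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    list(c(-p$la * y[1],
           p$la * y[1] - p$lr * y[2],
           p$lr * y[2]))
  }
  grid <- expand.grid(la = c(0.0064, 0.01),
                      lr = c(4.5e-5, 0.001, 0.0064 * (1 + 1e-9)))
  for (i in seq_len(nrow(grid))) {
    la <- grid$la[i]; lr <- min(grid$lr[i], grid$la[i]) # keep lr <= la
    tt <- c(50, 500, 2000)
    ode <- deSolve::lsoda(c(1, 0, 0), c(0, tt), rhs,
                          list(la = la, lr = lr),
                          rtol = 1e-12, atol = 1e-12)
    s <- alveolar_state(tt, la, lr)
    expect_lt(max(abs(s$n_inactive - ode[-1, 2])), 1e-8)
    expect_lt(max(abs(s$n_active - ode[-1, 3])), 1e-8)
    expect_lt(max(abs(s$n_retired - ode[-1, 4])), 1e-8)
  }
})

test_that("degenerate-rate limit joins the exact solution continuously", {
  la <- 0.005
  t <- c(10, 300, 1500)
  exact <- alveolar_state(t, la, la * (1 - 1e-7))$n_active   # exact branch
  limit <- alveolar_state(t, la, la * (1 - 1e-12))$n_active  # limit branch
  expect_equal(limit, exact, tolerance = 1e-6)
  expect_equal(limit, la * t * exp(-la * t), tolerance = 1e-10)
})

test_that("mean active fraction equals adaptive quadrature of N_A", {
  la <- 64e-4; lr <- 45e-6
  cases <- list(c(100, 114), c(0, 70.98), c(3000, 3010), c(7000, 7014))
  for (cs in cases) {
    q <- integrate(function(x) alveolar_state(x, la, lr)$n_active,
                   cs[1], cs[2], rel.tol = 1e-12)$value
    m <- mean_active_fraction(cs[1], cs[2], la, lr)
    expect_equal(m, q / diff(cs), tolerance = 1e-10)
    expect_true(m >= 0 && m <= 1)
  }
})

test_that("with no inactivation the mean active fraction increases with interval start", {
  m <- vapply(seq(0, 400, by = 50), function(t0)
    mean_active_fraction(t0, t0 + 10, 0.0064, 0), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("secretion over an interval matches quadrature and is linear in PL", {
  la <- 64e-4; lr <- 45e-6
  q <- integrate(function(x) alveolar_state(x, la, lr)$n_active,
                 0, 70.98, rel.tol = 1e-13)$value
  y <- secreted_between_sessions(0, 70.98, pl = 1.41, la, lr)
  expect_equal(y, 1.41 * q, tolerance = 1e-9)
  expect_identical(secreted_between_sessions(0, 70.98, 0, la, lr), 0)
  expect_equal(secreted_between_sessions(0, 70.98, 2.82, la, lr), 2 * y,
               tolerance = 1e-12)
})

test_that("domain errors are raised for invalid times and rates", {
  expect_error(alveolar_state(-1, 0.006, 0), "non-negative")
  expect_error(alveolar_state(10, -0.006, 0), "lambda_A")
  expect_error(mean_active_fraction(10, 10, 0.006, 0), "strictly greater")
  expect_error(mean_active_fraction(-1, 10, 0.006, 0), "non-negative")
})

test_that("late lactation is dominated by retired alveoli and secretion fades", {
  s <- alveolar_state(c(5e4, 5e5), lambda_A = 64e-4, lambda_R = 45e-6)
  expect_true(all(diff(s$n_retired) > 0))
  expect_gt(s$n_retired[2], 0.999)
  y_late <- secreted_between_sessions(5e5, 5e5 + 14, 1.41, 64e-4, 45e-6)
  expect_lt(y_late, 1e-6)
})
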
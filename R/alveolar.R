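#' Alveolar class proportions at a given time
#'
#' Closed-form solution of the three-class alveolar compartment model. The
#' udder's alveolar population is partitioned into non-activated, activated
#' and inactivated classes; non-activated alveoli activate at rate
#' `lambda_A` (per hour) and activated alveoli retire at rate `lambda_R`.
#' Starting from an all-non-activated population at lactation onset (`t = 0`),
#' the proportions are
#' \deqn{N_I(t) = e^{-\lambda_A t},\quad
#'       N_A(t) = \frac{\lambda_A}{\lambda_A-\lambda_R}
#'                \left(e^{-\lambda_R t} - e^{-\lambda_A t}\right),\quad
#'       N_R(t) = 1 - N_I(t) - N_A(t).}
#' When \eqn{\lambda_A \approx \lambda_R} the ratio is degenerate and the
#' analytic limit \eqn{N_A(t) = \lambda_A t e^{-\lambda_A t}} is used.
#'
#' @param t Hours since lactation onset (vectorised, `>= 0`).
#' @param lambda_A Alveolar activation rate, per hour (`> 0`).
#' @param lambda_R Alveolar inactivation rate, per hour (`>= 0`).
#'
#' @return A tibble with columns `t`, `n_inactive`, `n_active`, `n_retired`;
#'   the three proportions sum to 1 at every `t`.
#' @examples
#' alveolar_state(c(0, 100, 1000), lambda_A = 64e-4, lambda_R = 45e-6)
#' @export
alveolar_state <- function(t, lambda_A, lambda_R) {
  check_rates(lambda_A, lambda_R)
  if (any(t < 0)) abort("`t` must be non-negative (hours since lactation onset).")
  n_i <- exp(-lambda_A * t)
  n_a <- active_fraction(t, lambda_A, lambda_R)
  tibble::tibble(
    t = t,
    n_inactive = n_i,
    n_active = n_a,
    n_retired = 1 - n_i - n_a
  )
}

# N_A(t), with the analytic limit when lambda_A ~ lambda_R
active_fraction <- function(t, lambda_A, lambda_R) {
  if (rates_degenerate(lambda_A, lambda_R)) {
    return(lambda_A * t * exp(-lambda_A * t))
  }
  (lambda_A / (lambda_A - lambda_R)) * (exp(-lambda_R * t) - exp(-lambda_A * t))
}

rates_degenerate <- function(lambda_A, lambda_R) {
  abs(lambda_A - lambda_R) < 1e-10 * lambda_A
}

check_rates <- function(lambda_A, lambda_R) {
  if (lambda_A <= 0) abort("`lambda_A` must be > 0.")
  if (lambda_R < 0) abort("`lambda_R` must be >= 0.")
  invisible(NULL)
}

# integral over [t0, t1] of exp(-l * x); exact at l = 0, cancellation-safe
# through expm1 for small l * (t1 - t0)
w_term <- function(t0, t1, l) {
  if (l == 0) return(t1 - t0)
  exp(-l * t0) * (-expm1(-l * (t1 - t0))) / l
}

# integral of N_A over [t0, t1] (vectorised over t0, t1)
active_integral <- function(t0, t1, lambda_A, lambda_R) {
  if (rates_degenerate(lambda_A, lambda_R)) {
    l <- lambda_A
    return((t0 + 1 / l) * exp(-l * t0) - (t1 + 1 / l) * exp(-l * t1))
  }
  (lambda_A / (lambda_A - lambda_R)) *
    (w_term(t0, t1, lambda_R) - w_term(t0, t1, lambda_A))
}

#' Mean activated-alveoli proportion over a milking interval
#'
#' Time-average of the activated proportion \eqn{N_A} over the interval
#' between two consecutive milkings,
#' \deqn{E(MN_A(k)) = \frac{\int_{t(k-1)}^{t(k)} N_A(x)\,dx}{t(k)-t(k-1)},}
#' evaluated from the closed-form antiderivative (no quadrature).
#'
#' @param t_prev,t_now Interval bounds in hours since lactation onset
#'   (vectorised; `0 <= t_prev < t_now`).
#' @inheritParams alveolar_state
#' @return Numeric vector of mean activated proportions in `[0, 1]`.
#' @examples
#' mean_active_fraction(100, 114, lambda_A = 64e-4, lambda_R = 45e-6)
#' @export
mean_active_fraction <- function(t_prev, t_now, lambda_A, lambda_R) {
  check_rates(lambda_A, lambda_R)
  if (any(t_prev < 0)) abort("`t_prev` must be non-negative.")
  if (any(t_now <= t_prev)) abort("`t_now` must be strictly greater than `t_prev`.")
  active_integral(t_prev, t_now, lambda_A, lambda_R) / (t_now - t_prev)
}

#' Milk secreted between two milking sessions
#'
#' Expected milk production over a milking interval under the linearised
#' secretion model: the secretion-rate parameter `pl` (kg/h) times the
#' integral of the activated-alveoli proportion over the interval,
#' \deqn{Y_P(k) = PL \int_{t(k-1)}^{t(k)} N_A(x)\,dx.}
#' The alveolar compartment is taken to be empty at `t_prev`.
#'
#' @inheritParams mean_active_fraction
#' @param pl Secretion-rate parameter for the interval, kg per hour (`> 0`
#'   gives milk; `0` is allowed and yields 0 kg).
#' @return Kilograms secreted over the interval (vectorised).
#' @examples
#' secreted_between_sessions(0, 70.98, pl = 1.41,
#'                           lambda_A = 64e-4, lambda_R = 45e-6)
#' @export
secreted_between_sessions <- function(t_prev, t_now, pl, lambda_A, lambda_R) {
  if (any(pl < 0)) abort("`pl` must be non-negative.")
  pl * (t_now - t_prev) *
    mean_active_fraction(t_prev, t_now, lambda_A, lambda_R)
}
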
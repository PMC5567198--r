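# ---- parameter transforms ---------------------------------------------------
# Positive parameters:      theta = exp(alpha)
# Unit-interval parameters: theta = exp(-exp(alpha))  (decreasing in alpha)

#' Transform parameters to and from the unconstrained scale
#'
#' Maximum-likelihood fitting is done on unconstrained coordinates: a
#' positive parameter \eqn{\theta} is represented as
#' \eqn{\theta = e^{\alpha}} and a unit-interval parameter as
#' \eqn{\theta = e^{-e^{\alpha}}}, with \eqn{\alpha} real in both cases.
#' `to_alpha()` and `from_alpha()` are exact inverses.
#'
#' @param theta,alpha Numeric vectors on the natural / unconstrained scale.
#' @param transform Character vector (recycled): `"positive"` or
#'   `"unit_interval"`.
#' @return Numeric vector of the same length.
#' @examples
#' from_alpha(to_alpha(c(1.41, 0.54), c("positive", "unit_interval")),
#'            c("positive", "unit_interval"))
#' @export
to_alpha <- function(theta, transform) {
  transform <- rep_len(transform, length(theta))
  out <- numeric(length(theta))
  pos <- transform == "positive"
  uni <- transform == "unit_interval"
  if (any(!pos & !uni)) abort("unknown transform tag.")
  if (any(theta[pos] <= 0)) abort("positive-transform parameters must be > 0.")
  if (any(theta[uni] <= 0 | theta[uni] >= 1))
    abort("unit-interval parameters must lie strictly in (0, 1).")
  out[pos] <- log(theta[pos])
  out[uni] <- log(-log(theta[uni]))
  out
}

#' @rdname to_alpha
#' @export
from_alpha <- function(alpha, transform) {
  transform <- rep_len(transform, length(alpha))
  out <- numeric(length(alpha))
  pos <- transform == "positive"
  uni <- transform == "unit_interval"
  if (any(!pos & !uni)) abort("unknown transform tag.")
  out[pos] <- exp(alpha[pos])
  out[uni] <- exp(-exp(alpha[uni]))
  out
}

# ---- free-parameter bookkeeping --------------------------------------------
# A "spec" describes the free parameter vector of a fit: names, transform
# tags, and how to rebuild (milk_params, var_params) from a theta vector.
make_param_spec <- function(n_segments = 1L,
                            extreme_sessions = integer(0),
                            pl_breaks = NULL) {
  terms <- c("delta", "lambda_A", "lambda_R", "pi", "phi",
             paste0("pl_", seq_len(n_segments)))
  trans <- c("positive", "positive", "positive", "unit_interval",
             "unit_interval", rep("positive", n_segments))
  if (length(extreme_sessions)) {
    terms <- c(terms, "pi_extreme")
    trans <- c(trans, "unit_interval")
  }
  list(terms = terms, transform = trans, n_segments = n_segments,
       extreme_sessions = as.integer(extreme_sessions), pl_breaks = pl_breaks)
}

spec_to_params <- function(theta, spec, vp_template) {
  names(theta) <- spec$terms
  ov <- NULL
  if (length(spec$extreme_sessions))
    ov <- setNames(rep(theta[["pi_extreme"]], length(spec$extreme_sessions)),
                   as.character(spec$extreme_sessions))
  params <- milk_params(
    delta = theta[["delta"]],
    lambda_A = theta[["lambda_A"]],
    lambda_R = theta[["lambda_R"]],
    pi = theta[["pi"]],
    pi_overrides = ov,
    pl = unname(theta[paste0("pl_", seq_len(spec$n_segments))]),
    pl_breaks = spec$pl_breaks
  )
  vp <- vp_template
  vp$phi <- theta[["phi"]]
  list(params = params, vp = vp)
}

params_to_theta <- function(params, vp, spec) {
  th <- c(params$delta, params$lambda_A, params$lambda_R, params$pi, vp$phi,
          params$pl)
  if (length(spec$extreme_sessions))
    th <- c(th, unname(params$pi_overrides[1]))
  setNames(th, spec$terms)
}

# ---- log-likelihood ---------------------------------------------------------

#' Gaussian session-level log-likelihood
#'
#' Under a correct model the standardized residuals
#' \eqn{(Y_O(k) - E(Y_M(k)))/\sqrt{Var(Y_M(k))}} are standard normal, so the
#' observed yields carry the Gaussian log-likelihood
#' \deqn{\sum_k \left[-\tfrac12\log(2\pi Var(Y_M(k)))
#'       - \tfrac12 \frac{(Y_O(k)-E(Y_M(k)))^2}{Var(Y_M(k))}\right].}
#'
#' @param data A session tibble with columns `session`, `hours`, `label`,
#'   `yield` (observed kg).
#' @param params A [milk_params()] object.
#' @param vp A [var_params()] object.
#' @param interval_uncertainty Include the interval-duration variance
#'   component (nominal-schedule mode).
#' @return A finite scalar (larger is better).
#' @examples
#' d <- simulate_lactation(sim_config(n_days = 10, seed = 1))
#' sessions_log_lik(d, milk_params(), var_params())
#' @export
sessions_log_lik <- function(data, params, vp = var_params(),
                             interval_uncertainty = FALSE) {
  data <- check_session_frame(data, need_yield = TRUE)
  eng <- moment_engine(data$hours, data$label, params, vp,
                       interval_uncertainty = interval_uncertainty)
  if (any(!is.finite(eng$var_total)) || any(eng$var_total <= 0))
    abort("non-positive session variance under these parameters.")
  sum(dnorm(data$yield, eng$mean_measured, sqrt(eng$var_total), log = TRUE))
}

# negative log-likelihood on the alpha scale, with a large finite penalty for
# invalid parameter regions so the optimizer can recover
neg_log_lik_alpha <- function(alpha, spec, hours, label, yield, vp_template,
                              interval_uncertainty = FALSE) {
  theta <- from_alpha(alpha, spec$transform)
  pv <- try(spec_to_params(theta, spec, vp_template), silent = TRUE)
  if (inherits(pv, "try-error")) return(1e10)
  eng <- moment_engine(hours, label, pv$params, pv$vp,
                       interval_uncertainty = interval_uncertainty)
  v <- eng$var_total
  if (any(!is.finite(v)) || any(v <= 0)) return(1e10)
  ll <- sum(dnorm(yield, eng$mean_measured, sqrt(v), log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -ll
}
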
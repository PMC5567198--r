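# ---- internal moment engine -------------------------------------------------
# Computes, for every session k of a schedule, the mean-model quantities and
# the first two moments of produced / residual / extracted / measured yield,
# together with the named variance components. Plain vectors in and out:
# this is the inner loop of the likelihood and must stay lean.
#
# Recursions (retention rate pi(k) substituted per session):
#   E(Y_P) = PL(k) dt(k) E(MN_A(k))
#   Var(Y_P) = V_PL + V_PA
#     V_PL = PL_max dt E(MN_A) beta(1 - beta)
#     V_PA = (PL_max beta)^2 dt phi E(MN_A)(1 - E(MN_A))
#   T = E(Y_P) + E(Y_R(k-1))
#   E(Y_E) = (1 - pi) T ;  E(Y_R) = pi T
#   Var(Y_E) = T pi(1-pi) + (1-pi)^2 [Var(Y_P) + Var(Y_R(k-1))]
#   Var(Y_R) = T pi(1-pi) + pi^2     [Var(Y_P) + Var(Y_R(k-1))]
#   Var(Y_M) = E(Y_E)^2 CV^2 + Var(Y_E)  (+ V_tim in unknown-interval mode)
# Components: v_mes = E(Y_E)^2 CV^2 ; v_ret = T pi(1-pi) ;
#   v_rec = (1-pi)^2 Var(Y_R(k-1)) ; v_pro = (1-pi)^2 V_PL ;
#   v_alv = (1-pi)^2 V_PA. The carryover component enters with (1-pi)^2 --
#   the coefficient Var(Y_R(k-1)) actually carries in Var(Y_E) -- so that the
#   five (six) components sum to Var(Y_M) exactly.
moment_engine <- function(hours, label, params, vp,
                          interval_uncertainty = FALSE) {
  K <- length(hours)
  ex <- expand_params(params, K)
  t_now <- params$delta + hours
  t_prev <- c(0, t_now[-K])
  dt <- t_now - t_prev
  mna <- active_integral(t_prev, t_now, params$lambda_A, params$lambda_R) / dt

  pl_k <- ex$pl_k
  beta_k <- ex$beta_k
  pl_max <- ex$pl_max
  pi_k <- ex$pi_k

  e_yp <- pl_k * dt * mna
  v_pl <- pl_max * dt * mna * beta_k * (1 - beta_k)
  v_pa <- (pl_max * beta_k)^2 * dt * vp$phi * mna * (1 - mna)
  var_yp <- v_pl + v_pa

  v_tim <- numeric(K)
  if (interval_uncertainty) {
    dt_nom <- unname(vp$nominal_intervals[label])
    if (anyNA(dt_nom))
      abort("every session needs a morning/evening label in unknown-interval mode.")
    la <- params$lambda_A; lr <- params$lambda_R
    dYdT <- if (rates_degenerate(la, lr)) {
      # derivative of the degenerate-limit integral: N_A at t_prev + dt
      la * (t_prev + dt_nom) * exp(-la * (t_prev + dt_nom))
    } else {
      dw_r <- exp(-lr * t_prev) * exp(-lr * dt_nom)
      dw_a <- exp(-la * t_prev) * exp(-la * dt_nom)
      (la / (la - lr)) * (dw_r - dw_a)
    }
    v_tim <- (1 - pi_k)^2 * (pl_max * beta_k)^2 * dYdT^2 * vp$var_T
  }

  e_yr <- v_yr <- e_ye <- v_ye <- numeric(K)
  v_mes <- v_ret <- v_rec <- v_pro <- v_alv <- var_ym <- numeric(K)
  cv2 <- vp$cv_measurement^2
  eyr_prev <- 0
  vyr_prev <- 0
  for (k in seq_len(K)) {
    p <- pi_k[k]
    tt <- e_yp[k] + eyr_prev
    bin <- tt * p * (1 - p)
    one_m <- (1 - p)^2
    e_ye[k] <- (1 - p) * tt
    v_ye[k] <- bin + one_m * (var_yp[k] + vyr_prev)
    v_mes[k] <- e_ye[k]^2 * cv2
    v_ret[k] <- bin
    v_rec[k] <- one_m * vyr_prev
    v_pro[k] <- one_m * v_pl[k]
    v_alv[k] <- one_m * v_pa[k]
    var_ym[k] <- v_mes[k] + v_ye[k] + v_tim[k]
    e_yr[k] <- p * tt
    v_yr[k] <- bin + p^2 * (var_yp[k] + vyr_prev)
    eyr_prev <- e_yr[k]
    vyr_prev <- v_yr[k]
  }

  list(t = t_now, t_prev = t_prev, interval_h = dt, mna = mna,
       segment = ex$segment, beta = beta_k, pi = pi_k, pl = pl_k,
       mean_produced = e_yp, var_produced = var_yp,
       v_pl = v_pl, v_pa = v_pa,
       mean_residual = e_yr, var_residual = v_yr,
       mean_extracted = e_ye, var_extracted = v_ye,
       mean_measured = e_ye, var_total = var_ym,
       v_mes = v_mes, v_ret = v_ret, v_rec = v_rec,
       v_pro = v_pro, v_alv = v_alv, v_tim = v_tim)
}

# ---- exported surface -------------------------------------------------------

#' Deterministic per-session yield series
#'
#' Iterates the noise-free secretion / retention / extraction recursion over
#' a milking schedule: milk produced since the previous session, residual
#' milk retained (carryover), and milk extracted at each session, with
#' \eqn{Y_E(k) + Y_R(k) = Y_P(k) + Y_R(k-1)} (milk conservation) at every
#' session and `Y_R(0) = 0`.
#'
#' @param data A schedule tibble (see [milking_schedule()]).
#' @param params A [milk_params()] object.
#' @return The input tibble with columns `t` (hours since lactation onset),
#'   `y_produced`, `y_residual`, `y_extracted` (kg) appended.
#' @examples
#' extraction_series(nominal_schedule(10), milk_params())
#' @export
extraction_series <- function(data, params) {
  data <- check_session_frame(data)
  eng <- moment_engine(data$hours, data$label, params,
                       var_params(phi = 0))
  dplyr::bind_cols(
    data,
    tibble::tibble(t = eng$t,
                   y_produced = eng$mean_produced,
                   y_residual = eng$mean_residual,
                   y_extracted = eng$mean_extracted)
  )
}

#' Moments of per-interval milk production
#'
#' First two moments of the milk secreted over one interval: the mean
#' \eqn{E(Y_P(k)) = PL(k)\,\Delta t\,E(MN_A(k))} and the two production
#' variance terms — the secretion-proportion (binomial-type) term
#' \eqn{V_{PL}} and the activated-alveoli term \eqn{V_{PA}} scaled by the
#' dispersion factor `phi`.
#'
#' @inheritParams mean_active_fraction
#' @param pl_interval Secretion rate `PL(k)` for the interval (kg/h).
#' @param pl_max Lactation-wide maximum secretion rate (kg/h); `beta` is
#'   `pl_interval / pl_max`.
#' @param phi Dispersion factor in `(0, 1]`.
#' @return A tibble with columns `mean`, `v_pl`, `v_pa`, `variance`.
#' @examples
#' production_moments(100, 114, pl_interval = 1.32, pl_max = 1.41,
#'                    lambda_A = 64e-4, lambda_R = 45e-6, phi = 0.54)
#' @export
production_moments <- function(t_prev, t_now, pl_interval, pl_max,
                               lambda_A, lambda_R, phi) {
  if (any(pl_interval > pl_max))
    abort("`pl_interval` cannot exceed `pl_max`.")
  mna <- mean_active_fraction(t_prev, t_now, lambda_A, lambda_R)
  dt <- t_now - t_prev
  beta <- pl_interval / pl_max
  v_pl <- pl_max * dt * mna * beta * (1 - beta)
  v_pa <- (pl_max * beta)^2 * dt * phi * mna * (1 - mna)
  tibble::tibble(mean = pl_interval * dt * mna,
                 v_pl = v_pl, v_pa = v_pa, variance = v_pl + v_pa)
}

#' Propagate per-session yield moments and variance components
#'
#' Runs the coupled mean/variance recursion of the session-level model over
#' a schedule, returning for every session the expected measured yield, its
#' total variance, and the decomposition into named components: measurement
#' error (`v_mes`), milk retention (`v_ret`), milk carryover (`v_rec`),
#' secretion proportion (`v_pro`), activated-alveoli proportion (`v_alv`)
#' and, in unknown-interval mode, interval duration (`v_tim`). Components
#' sum to `var_total` at every session.
#'
#' @inheritParams extraction_series
#' @param vp A [var_params()] object.
#' @param interval_uncertainty If `TRUE`, session times are taken as nominal
#'   and the interval-duration variance component is added.
#' @return A tibble, one row per session, with moment and component columns.
#' @examples
#' m <- session_moments(nominal_schedule(6), milk_params(), var_params())
#' all.equal(m$var_total, m$v_mes + m$v_ret + m$v_rec + m$v_pro + m$v_alv)
#' @export
session_moments <- function(data, params, vp = var_params(),
                            interval_uncertainty = FALSE) {
  data <- check_session_frame(data)
  eng <- moment_engine(data$hours, data$label, params, vp,
                       interval_uncertainty = interval_uncertainty)
  dplyr::bind_cols(
    dplyr::select(data, "session", "hours", "label"),
    tibble::as_tibble(eng[c("t", "interval_h", "mna", "segment", "beta", "pi",
                            "mean_produced", "var_produced",
                            "mean_residual", "var_residual",
                            "mean_measured", "var_total",
                            "v_mes", "v_ret", "v_rec", "v_pro", "v_alv",
                            "v_tim")])
  )
}

#' Interval-duration variance component
#'
#' First-order (delta-method) variance of per-session yield with respect to
#' interval duration, used when exact milking times are unknown and only the
#' nominal interval lengths (14 h into morning, 10 h into evening sessions)
#' with variance `var_T` are available:
#' \deqn{V_{tim}(k) = (1-\pi)^2 [PL_{max} \beta(k)]^2
#'   \left[\tfrac{\lambda_A}{\lambda_A-\lambda_R}\right]^2
#'   (dw_R - dw_A)^2 \, Var_T,}
#' with \eqn{dw_R = e^{-\lambda_R t(k-1)} e^{-\lambda_R \Delta t(k)}} and
#' \eqn{dw_A} analogously.
#'
#' @param t_prev Session start time (hours since lactation onset).
#' @param label Session label, `"morning"` or `"evening"`.
#' @param params A [milk_params()] object (baseline retention used).
#' @param vp A [var_params()] object supplying `var_T` and nominal intervals.
#' @param beta Secretion proportion for the interval (default 1).
#' @return Variance contribution in kg^2.
#' @examples
#' timing_variance(200, "morning", milk_params(), var_params())
#' @export
timing_variance <- function(t_prev, label, params, vp = var_params(),
                            beta = 1) {
  if (!all(label %in% c("morning", "evening")))
    abort("`label` must be 'morning' or 'evening'.")
  dt_nom <- unname(vp$nominal_intervals[label])
  la <- params$lambda_A; lr <- params$lambda_R
  dYdT <- if (rates_degenerate(la, lr)) {
    la * (t_prev + dt_nom) * exp(-la * (t_prev + dt_nom))
  } else {
    dw_r <- exp(-lr * t_prev) * exp(-lr * dt_nom)
    dw_a <- exp(-la * t_prev) * exp(-la * dt_nom)
    (la / (la - lr)) * (dw_r - dw_a)
  }
  (1 - params$pi)^2 * (max(params$pl) * beta)^2 * dYdT^2 * vp$var_T
}

#' Variance-component shares
#'
#' Relative contribution of each variance component, per session and for the
#' whole lactation (lactation-level share of a component = its sum across
#' sessions divided by the summed total variance).
#'
#' @param moments A moments tibble from [session_moments()].
#' @return A list with `per_session` (tibble of per-session shares, summing
#'   to 1 in every row) and `overall` (one-row tibble of lactation-level
#'   shares).
#' @examples
#' m <- session_moments(nominal_schedule(20), milk_params(), var_params())
#' variance_shares(m)$overall
#' @export
variance_shares <- function(moments) {
  if (nrow(moments) == 0) abort("`moments` is empty.")
  comp <- c("v_mes", "v_ret", "v_rec", "v_pro", "v_alv", "v_tim")
  comp <- intersect(comp, names(moments))
  if (any(moments$var_total <= 0))
    abort("total variance is zero at some session; shares are undefined.")
  per <- dplyr::mutate(
    dplyr::select(moments, "session", dplyr::all_of(c("var_total", comp))),
    dplyr::across(dplyr::all_of(comp), ~ .x / .data$var_total,
                  .names = "share_{sub('v_', '', .col)}")
  )
  overall <- tibble::as_tibble(
    as.list(colSums(moments[comp]) / sum(moments$var_total))
  )
  names(overall) <- sub("^v_", "share_", names(overall))
  list(per_session = per, overall = overall)
}
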
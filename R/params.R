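#' Mean-model parameter set
#'
#' Bundles the estimable quantities of the mean yield model: the lactation
#' onset offset `delta` (hours between the start of lactation and the first
#' milking), the alveolar activation/inactivation rates, the baseline milk
#' retention rate with optional per-session overrides, and the
#' piecewise-constant secretion-rate parameter `PL(k)`.
#'
#' The retention rate is stored baseline-plus-overrides: `pi` applies to
#' every session except those named in `pi_overrides` (a numeric vector whose
#' names are session indices). `pl` holds one secretion rate per segment;
#' `pl_breaks` gives the session index at which each segment after the first
#' begins. When `pl_breaks` is `NULL` and more than one `pl` value is given,
#' segments of equal length are assumed at expansion time. The derived
#' secretion proportion is \eqn{\beta(k) = PL(k)/\max_k PL(k)}.
#'
#' Defaults are reference estimates for a healthy second-lactation dairy cow
#' milked twice daily over roughly 305 days: `delta = 70.98` h,
#' `lambda_A = 64e-4` /h, `lambda_R = 45e-6` /h, baseline retention 0.041
#' with extreme retention 0.28 at sessions 33 and 36, and five secretion-rate
#' segments at 1.41, 1.32, 1.16, 1.02 and 0.90 kg/h (secretion proportions
#' 1.00, 0.94, 0.82, 0.72, 0.64).
#'
#' @param delta Hours between lactation onset and first milking (`>= 0`).
#' @param lambda_A,lambda_R Activation / inactivation rates, per hour.
#' @param pi Baseline milk retention rate, in `[0, 1)`.
#' @param pi_overrides Named numeric vector of session-specific retention
#'   rates (names are session indices), or `NULL`.
#' @param pl Secretion-rate parameter(s), kg/h, one per segment.
#' @param pl_breaks Integer session indices opening segments 2..S, or `NULL`.
#'
#' @return An object of class `milk_params` (a named list).
#' @examples
#' p <- milk_params()
#' p$delta
#' milk_params(pl = 1.3, pi_overrides = NULL) # constant secretion rate
#' @export
milk_params <- function(delta = 70.98,
                        lambda_A = 64e-4,
                        lambda_R = 45e-6,
                        pi = 0.041,
                        pi_overrides = c("33" = 0.28, "36" = 0.28),
                        pl = c(1.41, 1.32, 1.16, 1.02, 0.90),
                        pl_breaks = NULL) {
  if (delta < 0) abort("`delta` must be >= 0 hours.")
  check_rates(lambda_A, lambda_R)
  if (pi < 0 || pi >= 1) abort("`pi` must lie in [0, 1).")
  if (!is.null(pi_overrides)) {
    if (is.null(names(pi_overrides)) || any(!nzchar(names(pi_overrides))))
      abort("`pi_overrides` must be a named vector (names = session indices).")
    if (any(pi_overrides < 0 | pi_overrides >= 1))
      abort("`pi_overrides` values must lie in [0, 1).")
  }
  if (any(pl <= 0)) abort("`pl` values must be > 0 kg/h.")
  if (!is.null(pl_breaks)) {
    pl_breaks <- as.integer(pl_breaks)
    if (length(pl_breaks) != length(pl) - 1L)
      abort("`pl_breaks` must have one entry per segment after the first.")
    if (is.unsorted(pl_breaks, strictly = TRUE) || any(pl_breaks < 2L))
      abort("`pl_breaks` must be strictly increasing session indices >= 2.")
  }
  structure(
    list(delta = delta, lambda_A = lambda_A, lambda_R = lambda_R,
         pi = pi, pi_overrides = pi_overrides,
         pl = pl, pl_breaks = pl_breaks),
    class = "milk_params"
  )
}

#' @export
print.milk_params <- function(x, ...) {
  cat("<milk_params>\n")
  cat(sprintf("  delta    : %.3f h\n", x$delta))
  cat(sprintf("  lambda_A : %.4g /h\n", x$lambda_A))
  cat(sprintf("  lambda_R : %.4g /h\n", x$lambda_R))
  cat(sprintf("  pi       : %.4g (baseline)", x$pi))
  if (length(x$pi_overrides))
    cat(sprintf("; overrides at sessions %s",
                paste(names(x$pi_overrides), collapse = ", ")))
  cat("\n")
  cat(sprintf("  pl       : %s kg/h (%d segment%s)\n",
              paste(format(x$pl, digits = 3), collapse = ", "),
              length(x$pl), if (length(x$pl) > 1) "s" else ""))
  invisible(x)
}

#' Variance-model parameter set
#'
#' Parameters of the per-session variance model: the measurement coefficient
#' of variation (fixed a priori at 0.025 unless overridden), the dispersion
#' factor `phi` scaling the activated-alveoli variance term (values below 1
#' express underdispersion from alveolar interdependence), and, for the
#' unknown-interval mode, the interval-duration variance `var_T` (h^2) and
#' the nominal interval lengths by session label (14 h into a morning
#' session, 10 h into an evening session).
#'
#' @param cv_measurement Measurement coefficient of variation (unitless, > 0).
#' @param phi Dispersion factor in `(0, 1]`.
#' @param var_T Variance of interval duration, h^2 (`>= 0`).
#' @param nominal_intervals Named numeric: nominal interval length (hours)
#'   preceding a `morning` and an `evening` session.
#'
#' @return An object of class `milk_var_params`.
#' @examples
#' var_params(phi = 0.54)
#' @export
var_params <- function(cv_measurement = 0.025,
                       phi = 0.54,
                       var_T = 0.25,
                       nominal_intervals = c(morning = 14, evening = 10)) {
  if (cv_measurement <= 0) abort("`cv_measurement` must be > 0.")
  if (phi < 0 || phi > 1) abort("`phi` must lie in (0, 1] (0 allowed as limit).")
  if (var_T < 0) abort("`var_T` must be >= 0.")
  if (!all(c("morning", "evening") %in% names(nominal_intervals)))
    abort("`nominal_intervals` needs named entries `morning` and `evening`.")
  structure(
    list(cv_measurement = cv_measurement, phi = phi, var_T = var_T,
         nominal_intervals = nominal_intervals),
    class = "milk_var_params"
  )
}

#' @export
print.milk_var_params <- function(x, ...) {
  cat("<milk_var_params>\n")
  cat(sprintf("  cv_measurement : %.4g\n", x$cv_measurement))
  cat(sprintf("  phi            : %.4g\n", x$phi))
  cat(sprintf("  var_T          : %.4g h^2\n", x$var_T))
  cat(sprintf("  nominal dt     : morning %.1f h, evening %.1f h\n",
              x$nominal_intervals[["morning"]], x$nominal_intervals[["evening"]]))
  invisible(x)
}

# Expand a milk_params object over K sessions: per-session retention pi_k,
# segment id, per-session PL(k), beta(k) and PL_max.
expand_params <- function(params, n_sessions) {
  K <- as.integer(n_sessions)
  pi_k <- rep(params$pi, K)
  ov <- params$pi_overrides
  if (length(ov)) {
    idx <- as.integer(names(ov))
    keep <- idx >= 1L & idx <= K
    pi_k[idx[keep]] <- unname(ov[keep])
  }
  S <- length(params$pl)
  if (S == 1L) {
    seg <- rep(1L, K)
  } else if (!is.null(params$pl_breaks)) {
    seg <- findInterval(seq_len(K), c(1L, params$pl_breaks))
  } else {
    seg <- rep(seq_len(S), each = ceiling(K / S), length.out = K)
  }
  pl_k <- params$pl[seg]
  pl_max <- max(params$pl)
  list(pi_k = pi_k, segment = seg, pl_k = pl_k,
       pl_max = pl_max, beta_k = pl_k / pl_max)
}

# Equal-length segment break positions for S segments over K sessions
equal_breaks <- function(n_segments, n_sessions) {
  if (n_segments < 2L) return(NULL)
  len <- ceiling(n_sessions / n_segments)
  as.integer(seq(len + 1L, by = len, length.out = n_segments - 1L))
}
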
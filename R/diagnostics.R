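#' Residual validation: normality and autocorrelation
#'
#' Kolmogorov-Smirnov test of the standardized residuals against the
#' standard normal (the residuals are already standardized by construction,
#' so no location/scale is estimated) and the Box-Pierce portmanteau test
#' \eqn{Q = n \sum_{j \le lag} \hat\rho_j^2 \sim \chi^2(lag)} for residual
#' autocorrelation.
#'
#' @param z Standardized residuals (at least 30).
#' @param lag Box-Pierce lag; default `min(20, floor(length(z)/4))`.
#' @return A one-row tibble: `ks_pvalue`, `box_pierce_pvalue`, `lag`.
#' @examples
#' validate_residuals(rnorm(200))
#' @export
validate_residuals <- function(z, lag = NULL) {
  if (length(z) < 30) abort("need at least 30 residuals.")
  if (sd(z) == 0) abort("residuals are constant; diagnostics undefined.")
  lag <- lag %||% min(20L, floor(length(z) / 4))
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  bp <- stats::Box.test(z, lag = lag, type = "Box-Pierce")
  tibble::tibble(ks_pvalue = unname(ks$p.value),
                 box_pierce_pvalue = unname(bp$p.value),
                 lag = as.integer(lag))
}

#' Aggregate session moments to daily means and variances
#'
#' Sums the morning and evening session means and variances of each day.
#' Valid as a variance only when the final model's residuals are
#' uncorrelated (check with [validate_residuals()]); days with a single
#' session are kept as-is. The day index defaults to `floor(hours/24) + 1`.
#'
#' @param moments A [session_moments()] tibble (an `observed` column, if
#'   present, is summed too).
#' @param day Optional integer vector assigning each session to a day.
#' @return A tibble with one row per day: `day`, `n_sessions`, `mean`,
#'   `variance` (and `observed` when available).
#' @examples
#' m <- session_moments(nominal_schedule(10), milk_params(), var_params())
#' aggregate_daily(m)
#' @export
aggregate_daily <- function(moments, day = NULL) {
  day <- day %||% (floor(moments$hours / 24) + 1L)
  out <- moments |>
    dplyr::mutate(day = day) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      mean = sum(.data$mean_measured),
      variance = sum(.data$var_total),
      dplyr::across(dplyr::any_of("observed"), sum),
      .groups = "drop")
  out
}

# centred moving average used for the peak of the (noisy) daily curve
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Whole-lactation goodness-of-fit summaries
#'
#' Pearson correlation of observed and fitted session yields, the
#' variance-explained ratio (summed model variance over the summed squared
#' residuals left after estimation; about 1 for a well-specified model),
#' lactation totals, and the peak of the daily curve. Because raw daily
#' values are noisy, the peak is located on a 7-day centred moving average
#' of the daily means.
#'
#' @param observed,fitted Aligned session-level yields (kg).
#' @param var_total Model variance per session (kg^2); needed for the
#'   variance-explained ratio.
#' @param daily Optional [aggregate_daily()] tibble for peak statistics.
#' @param peak_window Moving-average window in days for the peak (default 7).
#' @return A one-row tibble with `pearson_r`, `variance_explained_ratio`,
#'   `total_observed_kg`, `total_fitted_kg` and, when `daily` is given,
#'   `peak_day` and `peak_yield`.
#' @export
fit_summaries <- function(observed, fitted, var_total = NULL, daily = NULL,
                          peak_window = 7) {
  if (length(observed) != length(fitted))
    abort("`observed` and `fitted` must have the same length.")
  out <- tibble::tibble(
    pearson_r = cor(observed, fitted),
    variance_explained_ratio =
      if (is.null(var_total)) NA_real_
      else sum(var_total) / sum((observed - fitted)^2),
    total_observed_kg = sum(observed),
    total_fitted_kg = sum(fitted)
  )
  if (!is.null(daily)) {
    sm <- moving_average(daily$mean, peak_window)
    out$peak_day <- daily$day[which.max(sm)]
    out$peak_yield <- max(sm)
  }
  out
}
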
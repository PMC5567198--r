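#' Plot observed versus fitted session yields
#'
#' @param object A `milking_fit` or `lactation_fit`.
#' @param ... Unused.
#' @return A ggplot: observed yields (points), fitted means (line) and the
#'   95% band from the model variance.
#' @method autoplot milking_fit
#' @export
autoplot.milking_fit <- function(object, ...) {
  r <- object$residuals
  ggplot2::ggplot(r, ggplot2::aes(x = .data$session)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - 1.96 * .data$sd,
                                      ymax = .data$fitted + 1.96 * .data$sd),
                         fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "darkgreen") +
    ggplot2::labs(x = "milking session", y = "yield (kg)",
                  title = "Observed and fitted session yields") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.milking_fit
#' @method autoplot lactation_fit
#' @export
autoplot.lactation_fit <- function(object, ...) {
  p <- autoplot(object$fit)
  if (length(object$elements$segment_boundaries))
    p <- p + ggplot2::geom_vline(
      xintercept = object$elements$segment_boundaries,
      linetype = "dashed", colour = "steelblue", linewidth = 0.3)
  if (length(object$elements$extreme_sessions))
    p <- p + ggplot2::geom_vline(
      xintercept = object$elements$extreme_sessions,
      linetype = "dotted", colour = "firebrick", linewidth = 0.3)
  p
}

#' Residual diagnostics panel
#'
#' Empirical cumulative distribution of the standardized residuals overlaid
#' with the standard-normal CDF.
#'
#' @param fit A `milking_fit` or `lactation_fit`.
#' @return A ggplot.
#' @export
plot_residual_ecdf <- function(fit) {
  if (inherits(fit, "lactation_fit")) fit <- fit$fit
  z <- sort(fit$residuals$z)
  df <- tibble::tibble(z = z, ecdf = seq_along(z) / length(z),
                       normal = pnorm(z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ecdf)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$normal), colour = "firebrick") +
    ggplot2::labs(x = "standardized residual", y = "cumulative probability",
                  title = "Residual ECDF vs standard normal") +
    ggplot2::theme_minimal()
}

#' Per-session variance-component shares
#'
#' Stacked view of the relative contribution of each variance component
#' across the lactation.
#'
#' @param moments A [session_moments()] tibble.
#' @return A ggplot.
#' @export
plot_variance_shares <- function(moments) {
  shares <- variance_shares(moments)$per_session
  long <- tidyr::pivot_longer(shares,
                              dplyr::starts_with("share_"),
                              names_to = "component",
                              names_prefix = "share_",
                              values_to = "share")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$session, y = .data$share,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "milking session", y = "share of total variance",
                  title = "Variance decomposition across the lactation") +
    ggplot2::theme_minimal()
}
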
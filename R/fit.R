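#' Fit the milking-session model by maximum likelihood
#'
#' Maximises the Gaussian session-level likelihood over the unconstrained
#' (transformed) parameter scale with [stats::nlm()], and derives 95%
#' confidence intervals from the inverse Hessian at the optimum (normality
#' of the ML estimator on the transformed scale; bounds back-transformed).
#' Free parameters: `delta`, `lambda_A`, `lambda_R`, baseline retention
#' `pi`, dispersion `phi`, one secretion rate per segment and, when
#' `extreme_sessions` is non-empty, one shared extreme retention rate.
#'
#' @param data Session tibble with `session`, `hours`, `label`, `yield`.
#' @param pl_breaks Session indices opening secretion-rate segments 2..S
#'   (`NULL` for a single constant secretion rate).
#' @param extreme_sessions Integer session indices given the shared extreme
#'   retention rate (empty for none).
#' @param vp A [var_params()] template; its `phi` entry is re-estimated,
#'   `cv_measurement`, `var_T` and the nominal intervals are held fixed.
#' @param interval_uncertainty Fit in unknown-interval mode (adds the
#'   interval-duration variance component, nominal schedule).
#' @param init Optional named list of starting values overriding the
#'   defaults (`delta` 72 h, `lambda_A` 5e-3, `lambda_R` 5e-5, `pi` 0.05,
#'   `phi` 0.5, `pl` max session yield / 10 h).
#' @param iterlim Maximum `nlm` iterations.
#' @return A `milking_fit` object: estimates with CIs ([tidy()]),
#'   log-likelihood and diagnostics ([glance()]), standardized residuals
#'   (`$residuals`), transformed-scale covariance (`$vcov_alpha`), the
#'   fitted [milk_params()]/[var_params()] and convergence metadata.
#' @seealso [fit_lactation()] for the two-stage workflow with
#'   conditional-element detection.
#' @examples
#' d <- simulate_lactation(sim_config(n_days = 30, seed = 1))
#' f <- fit_milking_model(d)
#' tidy(f)
#' @export
fit_milking_model <- function(data,
                              pl_breaks = NULL,
                              extreme_sessions = integer(0),
                              vp = var_params(),
                              interval_uncertainty = FALSE,
                              init = NULL,
                              iterlim = 400) {
  data <- check_session_frame(data, need_yield = TRUE)
  K <- nrow(data)
  if (K < 20) abort("at least 20 sessions are required to fit the model.")
  n_segments <- length(pl_breaks) + 1L
  spec <- make_param_spec(n_segments, extreme_sessions, pl_breaks)

  start <- list(delta = 72, lambda_A = 5e-3, lambda_R = 5e-5,
                pi = 0.05, phi = 0.5,
                pl = rep(max(data$yield) / 10, n_segments),
                pi_extreme = 0.2)
  if (!is.null(init)) start[names(init)] <- init
  theta0 <- c(start$delta, start$lambda_A, start$lambda_R, start$pi,
              start$phi, rep_len(start$pl, n_segments))
  if (length(extreme_sessions)) theta0 <- c(theta0, start$pi_extreme)
  alpha0 <- to_alpha(theta0, spec$transform)

  opt <- suppressWarnings(nlm(
    neg_log_lik_alpha, alpha0,
    spec = spec, hours = data$hours, label = data$label, yield = data$yield,
    vp_template = vp, interval_uncertainty = interval_uncertainty,
    hessian = TRUE, iterlim = iterlim, gradtol = 1e-7, steptol = 1e-9
  ))
  if (opt$code >= 4)
    warn(sprintf("nlm did not converge cleanly (code %d).", opt$code))

  alpha_hat <- opt$estimate
  theta_hat <- from_alpha(alpha_hat, spec$transform)

  # identifiability guard: relabel if activation/inactivation rates crossed
  # (Y_P is invariant under swapping the rates with PL scaled by lambda_A /
  # lambda_R, so the labels are fixed by the convention lambda_A > lambda_R)
  i_a <- match("lambda_A", spec$terms); i_r <- match("lambda_R", spec$terms)
  if (theta_hat[i_a] < theta_hat[i_r]) {
    scale_pl <- theta_hat[i_a] / theta_hat[i_r]
    tmp <- theta_hat[i_a]; theta_hat[i_a] <- theta_hat[i_r]; theta_hat[i_r] <- tmp
    ipl <- grep("^pl_", spec$terms)
    theta_hat[ipl] <- theta_hat[ipl] * scale_pl
    alpha_hat <- to_alpha(theta_hat, spec$transform)
    warn("activation/inactivation rates crossed; relabelled with lambda_A > lambda_R.")
  }

  # Hessian-inverse covariance on the transformed scale
  vcov_alpha <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se_alpha <- rep(NA_real_, length(alpha_hat))
  if (!is.null(vcov_alpha)) {
    dg <- diag(vcov_alpha)
    ok <- is.finite(dg) & dg > 0
    se_alpha[ok] <- sqrt(dg[ok])
  }

  z975 <- qnorm(0.975)
  lo_a <- alpha_hat - z975 * se_alpha
  hi_a <- alpha_hat + z975 * se_alpha
  ci1 <- from_alpha(lo_a, spec$transform)
  ci2 <- from_alpha(hi_a, spec$transform)
  estimates <- tibble::tibble(
    term = spec$terms,
    estimate = unname(theta_hat),
    transform = spec$transform,
    alpha = unname(alpha_hat),
    se_alpha = unname(se_alpha),
    conf.low = pmin(ci1, ci2),
    conf.high = pmax(ci1, ci2)
  )

  pv <- spec_to_params(theta_hat, spec, vp)
  eng <- moment_engine(data$hours, data$label, pv$params, pv$vp,
                       interval_uncertainty = interval_uncertainty)
  resid <- tibble::tibble(
    session = data$session,
    observed = data$yield,
    fitted = eng$mean_measured,
    sd = sqrt(eng$var_total),
    z = (data$yield - eng$mean_measured) / sqrt(eng$var_total)
  )

  structure(
    list(estimates = estimates,
         params = pv$params,
         var_params = pv$vp,
         log_lik = -opt$minimum,
         vcov_alpha = vcov_alpha,
         residuals = resid,
         data = data,
         spec = spec,
         interval_uncertainty = interval_uncertainty,
         convergence = list(code = opt$code, iterations = opt$iterations,
                            gradient = opt$gradient,
                            gradient_norm = sqrt(sum(opt$gradient^2)))),
    class = "milking_fit"
  )
}

#' Two-stage fitting workflow with conditional-element discovery
#'
#' Stage 1 fits the model with a constant secretion rate and a single
#' retention rate. Its standardized residuals are then screened for the two
#' conditional-element types: sessions with extreme retention
#' ([detect_extreme_retention()], two-sided tail probability below
#' `alpha_extreme`) and secretion-rate regime changes
#' ([detect_beta_segments()], mean/variance changepoints at
#' `alpha_changepoint`). Stage 3 refits with one secretion rate per detected
#' segment and a shared extreme retention rate for the flagged sessions.
#'
#' A flagged session is attributed an extreme *retention* rate only when its
#' residual is negative (milk held back); a flagged positive residual
#' immediately after a retention spike is the carryover being recovered and
#' is explained by the model itself, so it receives no override.
#'
#' @inheritParams fit_milking_model
#' @param alpha_extreme Two-sided tail probability below which a residual is
#'   an extreme-retention flag (default 0.001).
#' @param alpha_changepoint Significance level of the changepoint
#'   segmentation (default 0.05).
#' @param min_segment Minimum changepoint segment length in sessions.
#' @param conditional_elements Set `FALSE` to stop after stage 1.
#' @return A `lactation_fit` object: the final `milking_fit` (`$fit`), the
#'   stage-1 fit (`$stage1`) and the detected element set (`$elements`, see
#'   [conditional_elements_set()]). `tidy()`/`glance()`/`autoplot()` apply
#'   to the final fit.
#' @examples
#' \donttest{
#' d <- simulate_lactation(sim_config(n_days = 120, seed = 7))
#' w <- fit_lactation(d)
#' w$elements
#' }
#' @export
fit_lactation <- function(data,
                          vp = var_params(),
                          interval_uncertainty = FALSE,
                          alpha_extreme = 0.001,
                          alpha_changepoint = 0.05,
                          min_segment = 30,
                          conditional_elements = TRUE,
                          init = NULL,
                          iterlim = 400) {
  stage1 <- fit_milking_model(data, vp = vp,
                              interval_uncertainty = interval_uncertainty,
                              init = init, iterlim = iterlim)
  if (!conditional_elements) {
    return(structure(list(fit = stage1, stage1 = stage1,
                          elements = conditional_elements_set(integer(0),
                                                              integer(0),
                                                              nrow(data))),
                     class = "lactation_fit"))
  }
  z <- stage1$residuals$z
  elements <- tryCatch({
    flagged <- detect_extreme_retention(z, alpha = alpha_extreme)
    retention_flags <- flagged[z[flagged] < 0]
    boundaries <- detect_beta_segments(z, alpha = alpha_changepoint,
                                       min_segment = min_segment,
                                       exclude = flagged)
    conditional_elements_set(retention_flags, boundaries, length(z))
  }, error = function(e) {
    warn(paste0("conditional-element detection failed (", conditionMessage(e),
                "); returning the stage-1 fit."))
    NULL
  })
  if (is.null(elements))
    return(structure(list(fit = stage1, stage1 = stage1,
                          elements = conditional_elements_set(integer(0),
                                                              integer(0),
                                                              nrow(data))),
                     class = "lactation_fit"))

  if (!length(elements$extreme_sessions) && !length(elements$segment_boundaries))
    return(structure(list(fit = stage1, stage1 = stage1, elements = elements),
                     class = "lactation_fit"))

  # stage 3: segment-wise PL and flagged retention, warm-started from stage 1
  est1 <- setNames(stage1$estimates$estimate, stage1$estimates$term)
  seg_id <- findInterval(data$session, c(1L, elements$segment_boundaries))
  ratio <- vapply(seq_len(elements$n_segments), function(s) {
    i <- seg_id == s
    sum(stage1$residuals$observed[i]) / sum(stage1$residuals$fitted[i])
  }, numeric(1))
  init3 <- list(delta = est1[["delta"]], lambda_A = est1[["lambda_A"]],
                lambda_R = est1[["lambda_R"]], pi = est1[["pi"]],
                phi = est1[["phi"]],
                pl = pmax(est1[["pl_1"]] * ratio, 1e-3),
                pi_extreme = 0.2)
  fit3 <- tryCatch(
    fit_milking_model(data,
                      pl_breaks = elements$segment_boundaries,
                      extreme_sessions = elements$extreme_sessions,
                      vp = vp, interval_uncertainty = interval_uncertainty,
                      init = init3, iterlim = iterlim),
    error = function(e) {
      warn(paste0("stage-3 refit failed (", conditionMessage(e),
                  "); returning the stage-1 fit."))
      stage1
    })
  structure(list(fit = fit3, stage1 = stage1, elements = elements),
            class = "lactation_fit")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.milking_fit <- function(x, ...) {
  cat("<milking_fit> ", nrow(x$data), " sessions, log-likelihood ",
      format(x$log_lik, digits = 8), "\n", sep = "")
  cat(sprintf("  convergence code %d after %d iterations\n",
              x$convergence$code, x$convergence$iterations))
  print(x$estimates, n = nrow(x$estimates))
  invisible(x)
}

#' @export
print.lactation_fit <- function(x, ...) {
  cat("<lactation_fit>\n")
  print(x$elements)
  print(x$fit)
  invisible(x)
}

#' Tidy method for milking-session fits
#'
#' @param x A `milking_fit` or `lactation_fit` object.
#' @param ... Unused.
#' @return A tibble of parameter estimates with transformed-scale standard
#'   errors and back-transformed 95% confidence bounds.
#' @method tidy milking_fit
#' @export
tidy.milking_fit <- function(x, ...) x$estimates

#' @rdname tidy.milking_fit
#' @method tidy lactation_fit
#' @export
tidy.lactation_fit <- function(x, ...) tidy(x$fit)

#' Glance method for milking-session fits
#'
#' One-row model summary: log-likelihood, number of sessions and free
#' parameters, convergence, the variance-explained ratio (model variance
#' over residual variance) and the residual diagnostics p-values.
#'
#' @inheritParams tidy.milking_fit
#' @return A one-row tibble.
#' @method glance milking_fit
#' @export
glance.milking_fit <- function(x, ...) {
  dg <- validate_residuals(x$residuals$z)
  tibble::tibble(
    logLik = x$log_lik,
    nobs = nrow(x$data),
    n_parameters = nrow(x$estimates),
    convergence_code = x$convergence$code,
    variance_explained_ratio =
      sum(x$residuals$sd^2) / sum((x$residuals$observed - x$residuals$fitted)^2),
    ks_pvalue = dg$ks_pvalue,
    box_pierce_pvalue = dg$box_pierce_pvalue,
    pearson_r = cor(x$residuals$observed, x$residuals$fitted)
  )
}

#' @rdname glance.milking_fit
#' @method glance lactation_fit
#' @export
glance.lactation_fit <- function(x, ...) glance(x$fit)

#' Fitted session moments of a milking fit
#'
#' @param fit A `milking_fit` or `lactation_fit`.
#' @return The [session_moments()] tibble at the fitted parameters.
#' @export
fitted_moments <- function(fit) {
  if (inherits(fit, "lactation_fit")) fit <- fit$fit
  session_moments(fit$data, fit$params, fit$var_params,
                  interval_uncertainty = fit$interval_uncertainty)
}
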
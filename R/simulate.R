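#' Configuration for the synthetic-lactation simulator
#'
#' Bundles everything the generative engine needs: the true mean and
#' variance parameters, the lactation length, the twice-daily schedule
#' geometry (mean intervals of 14 h evening-to-morning and 10 h
#' morning-to-evening, jittered with variance `var_T`), and switches for
#' the three noise layers. Defaults reproduce the reference study
#' conditions: a 305-day lactation (610 sessions) at the [milk_params()]
#' and [var_params()] defaults.
#'
#' @param n_days Lactation length in days (two sessions per day).
#' @param params True [milk_params()].
#' @param vp True [var_params()]; `var_T` is also the schedule jitter
#'   variance (h^2).
#' @param first_label Label of the first session.
#' @param production_noise,retention_noise,measurement_noise Logical
#'   switches for the per-interval secretion noise, the binomial-type
#'   retention split noise and the log-normal measurement error.
#' @param jitter_intervals Draw interval lengths around their nominal means
#'   (variance `var_T`); set `FALSE` for the exact 14/10 grid.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_days = 60, seed = 1)
#' @export
sim_config <- function(n_days = 305,
                       params = milk_params(),
                       vp = var_params(),
                       first_label = "morning",
                       production_noise = TRUE,
                       retention_noise = TRUE,
                       measurement_noise = TRUE,
                       jitter_intervals = TRUE,
                       seed = NULL) {
  if (n_days < 1) abort("`n_days` must be >= 1.")
  structure(list(n_days = as.integer(n_days), params = params, vp = vp,
                 first_label = match.arg(first_label,
                                         c("morning", "evening")),
                 production_noise = production_noise,
                 retention_noise = retention_noise,
                 measurement_noise = measurement_noise,
                 jitter_intervals = jitter_intervals,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a twice-daily milking schedule
#'
#' Alternating morning/evening sessions on the nominal grid (14 h into a
#' morning session, 10 h into an evening session). Session times are
#' jittered around that grid — milking is anchored to the farm's clock, so
#' the clock does not drift over the lactation — with per-session noise
#' scaled so that each interval duration has variance `var_T`.
#'
#' @param config A [sim_config()].
#' @return A schedule tibble (see [milking_schedule()]).
#' @examples
#' simulate_schedule(sim_config(n_days = 3, seed = 1))
#' @export
simulate_schedule <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- 2L * config$n_days
  lab <- if (config$first_label == "morning")
    rep(c("morning", "evening"), length.out = K)
  else rep(c("evening", "morning"), length.out = K)
  grid <- c(0, cumsum(unname(config$vp$nominal_intervals[lab[-1]])))
  hours <- if (config$jitter_intervals) {
    # independent session-time noise: interval = nominal + (e_k - e_{k-1}),
    # so Var(interval) = 2 * Var(e) = var_T
    e <- c(0, rnorm(K - 1L, 0, sqrt(config$vp$var_T / 2)))
    h <- grid + e
    for (k in seq_len(K - 1L) + 1L)           # keep sessions >= 1 h apart
      if (h[k] < h[k - 1L] + 1) h[k] <- h[k - 1L] + 1
    h
  } else grid
  milking_schedule(hours, label = lab)
}

# Gamma draw matched to (mean, variance); degenerate variance -> mean
draw_gamma <- function(n, mean, variance) {
  out <- rep(mean, length.out = n)
  ok <- variance > 0 & mean > 0
  if (any(ok)) {
    shape <- mean[ok]^2 / variance[ok]
    out[ok] <- rgamma(sum(ok), shape = shape, rate = shape / mean[ok])
  }
  out
}

# Beta draw for the retention fraction: mean p, variance p(1-p)/total
# (the per-kg binomial split of the realized available milk). Falls back to
# the deterministic mean when the total is too small for a proper Beta.
draw_retention_fraction <- function(p, total) {
  if (p <= 0) return(0)
  nu <- total - 1
  if (nu <= 0.05) return(p)
  rbeta(1, shape1 = p * nu, shape2 = (1 - p) * nu)
}

#' Simulate a synthetic lactation
#'
#' Generates per-session observed yields from the session-level model:
#' milk produced over each interval is drawn from a Gamma distribution
#' matched to the model's production mean and variance (secretion-proportion
#' and dispersion-scaled activated-alveoli terms); the available milk is
#' split between extraction and retention by a Beta-distributed retention
#' fraction whose variance reproduces the binomial-type retention term
#' conditional on the realized total; and the measured yield multiplies the
#' extracted milk by a log-normal measurement error with coefficient of
#' variation `cv_measurement`. With all noise switches off the series equals
#' the deterministic [extraction_series()].
#'
#' @param config A [sim_config()].
#' @return A session tibble (`session`, `hours`, `label`, `yield`) with the
#'   generating truth attached as attributes `truth` (list with `params`,
#'   `vp`, `config`) and `latent` (tibble of the latent produced / retained
#'   / extracted series).
#' @examples
#' d <- simulate_lactation(sim_config(n_days = 20, seed = 42))
#' head(d)
#' @export
simulate_lactation <- function(config) {
  sched <- simulate_schedule(config)       # consumes config$seed if set
  params <- config$params
  vp <- config$vp
  K <- nrow(sched)
  eng <- moment_engine(sched$hours, sched$label, params, vp)

  yp <- if (config$production_noise)
    draw_gamma(K, eng$mean_produced, eng$var_produced)
  else eng$mean_produced

  pi_k <- eng$pi
  y_res <- y_ext <- numeric(K)
  carry <- 0
  for (k in seq_len(K)) {
    total <- yp[k] + carry
    f <- if (config$retention_noise)
      draw_retention_fraction(pi_k[k], total)
    else pi_k[k]
    y_res[k] <- f * total
    y_ext[k] <- (1 - f) * total
    carry <- y_res[k]
  }

  yield <- if (config$measurement_noise)
    y_ext * exp(rnorm(K, 0, vp$cv_measurement))
  else y_ext

  out <- dplyr::mutate(sched, yield = yield)
  attr(out, "truth") <- list(params = params, vp = vp, config = config)
  attr(out, "latent") <- tibble::tibble(session = sched$session,
                                        y_produced = yp,
                                        y_residual = y_res,
                                        y_extracted = y_ext)
  out
}

#' Parameter-recovery harness
#'
#' Simulates replicate lactations at a known truth, fits each one (either
#' the full two-stage workflow or the stage-1 model) and reports
#' per-parameter bias, RMSE and 95% confidence-interval coverage. The
#' derived maximum secretion rate `pl_max` is summarised from the largest
#' per-segment estimate.
#'
#' @param config A [sim_config()] holding the truth.
#' @param n_replicates Number of simulated lactations.
#' @param seed Integer; replicate r uses seed `seed + r`.
#' @param workflow `"two_stage"` (detection + refit) or `"stage1"`.
#' @param ... Passed on to [fit_lactation()].
#' @return A list with `replicates` (tibble of per-replicate estimates and
#'   CIs) and `summary` (tibble with `term`, `truth`, `median`, `bias`,
#'   `rmse`, `coverage`).
#' @examples
#' \donttest{
#' rec <- recovery_harness(sim_config(n_days = 100), n_replicates = 3,
#'                         seed = 1)
#' rec$summary
#' }
#' @export
recovery_harness <- function(config, n_replicates = 20, seed = 1,
                             workflow = c("two_stage", "stage1"), ...) {
  workflow <- match.arg(workflow)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  truth <- c(delta = config$params$delta,
             lambda_A = config$params$lambda_A,
             lambda_R = config$params$lambda_R,
             pi = config$params$pi,
             phi = config$vp$phi,
             pl_max = max(config$params$pl))
  if (length(config$params$pi_overrides))
    truth <- c(truth, pi_extreme = unname(config$params$pi_overrides[1]))

  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- seed + r
    d <- simulate_lactation(cfg)
    ft <- if (workflow == "two_stage") fit_lactation(d, vp = config$vp, ...)
          else fit_lactation(d, vp = config$vp, conditional_elements = FALSE,
                             ...)
    est <- tidy(ft)
    pl_rows <- est[grepl("^pl_", est$term), ]
    imax <- which.max(pl_rows$estimate)
    keep <- est[est$term %in% c("delta", "lambda_A", "lambda_R", "pi", "phi",
                                "pi_extreme"), ]
    plmax_row <- pl_rows[imax, ]
    plmax_row$term <- "pl_max"
    dplyr::bind_rows(keep, plmax_row) |>
      dplyr::mutate(replicate = r) |>
      dplyr::select("replicate", "term", "estimate", "conf.low", "conf.high")
  }
  reps <- purrr::map_dfr(seq_len(n_replicates), one_rep)
  reps$truth <- unname(truth[reps$term])
  reps$covered <- !is.na(reps$truth) & !is.na(reps$conf.low) &
    !is.na(reps$conf.high) &
    reps$conf.low <= reps$truth & reps$truth <= reps$conf.high

  summary <- reps |>
    dplyr::filter(!is.na(.data$truth)) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      median = median(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      .groups = "drop")
  list(replicates = reps, summary = summary)
}
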
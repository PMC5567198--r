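# Reference study conditions used across the suite: a second-lactation
# twice-daily cow, 305 days, with the published-scale parameter estimates.
ref_params <- function(...) milk_params(...)

ref_var_params <- function(...) var_params(...)

# constant-secretion, no-override variant (well-specified stage-1 truth)
flat_params <- function(pl = 1.41) {
  milk_params(pl = pl, pi_overrides = NULL)
}

# short deterministic schedule helper
ref_schedule <- function(n_sessions = 20) nominal_schedule(n_sessions)

# Monte-Carlo oracle for the propagated session moments: simulates the
# generative chain with *normal* production and retention-split noise
# matched to the model's means/variances (a distribution-free check of the
# moment recursion, independent of the package simulator's Gamma/Beta
# families). Vectorised across replicates.
mc_chain_moments <- function(schedule, params, vp, n_rep = 1e5) {
  eng <- lactmod:::moment_engine(schedule$hours, schedule$label, params, vp)
  K <- nrow(schedule)
  ym <- matrix(0, n_rep, K)
  carry <- numeric(n_rep)
  for (k in seq_len(K)) {
    yp <- rnorm(n_rep, eng$mean_produced[k], sqrt(eng$var_produced[k]))
    total <- yp + carry
    p <- eng$pi[k]
    ret <- p * total + rnorm(n_rep, 0, sqrt(pmax(total, 0) * p * (1 - p)))
    ext <- total - ret
    ym[, k] <- ext * exp(rnorm(n_rep, 0, vp$cv_measurement))
    carry <- ret
  }
  list(mean = colMeans(ym), var = apply(ym, 2, var))
}
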
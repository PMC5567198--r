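#' Conditional-element set
#'
#' Container for the two residual-discovered conditional-element types:
#' sessions with extreme milk retention and the boundaries of
#' secretion-rate (beta) segments.
#'
#' @param extreme_sessions Integer session indices flagged for extreme
#'   retention.
#' @param segment_boundaries Strictly increasing integer indices of the
#'   first session of each segment after the first.
#' @param n_sessions Total number of sessions K.
#' @return An object of class `conditional_elements`.
#' @export
conditional_elements_set <- function(extreme_sessions, segment_boundaries,
                                     n_sessions) {
  extreme_sessions <- sort(unique(as.integer(extreme_sessions)))
  segment_boundaries <- sort(unique(as.integer(segment_boundaries)))
  if (length(extreme_sessions) &&
      (min(extreme_sessions) < 1L || max(extreme_sessions) > n_sessions))
    abort("`extreme_sessions` must lie in 1..K.")
  if (length(segment_boundaries) &&
      (min(segment_boundaries) < 2L || max(segment_boundaries) > n_sessions))
    abort("`segment_boundaries` must lie in 2..K.")
  structure(list(extreme_sessions = extreme_sessions,
                 segment_boundaries = segment_boundaries,
                 n_segments = length(segment_boundaries) + 1L,
                 n_sessions = as.integer(n_sessions)),
            class = "conditional_elements")
}

#' @export
print.conditional_elements <- function(x, ...) {
  cat("<conditional_elements> ")
  cat(sprintf("%d segment%s", x$n_segments, if (x$n_segments > 1) "s" else ""))
  if (length(x$segment_boundaries))
    cat(" (boundaries at ", paste(x$segment_boundaries, collapse = ", "), ")",
        sep = "")
  if (length(x$extreme_sessions))
    cat("; extreme retention at session(s) ",
        paste(x$extreme_sessions, collapse = ", "), sep = "")
  else cat("; no extreme-retention sessions")
  cat("\n")
  invisible(x)
}

#' Flag sessions with extreme retention from standardized residuals
#'
#' A session is flagged when its standardized residual is too improbable
#' under the standard normal: two-sided tail probability
#' \eqn{2\Phi(-|z|) < \alpha} (default \eqn{\alpha = 0.001}, i.e.
#' \eqn{|z| > 3.29}). Deterministic given the input.
#'
#' @param z Numeric vector of standardized residuals (one per session).
#' @param alpha Two-sided tail-probability threshold.
#' @return Integer vector of flagged session indices (possibly empty).
#' @examples
#' z <- rnorm(100); z[33] <- -4
#' detect_extreme_retention(z)
#' @export
detect_extreme_retention <- function(z, alpha = 0.001) {
  if (length(z) == 0) abort("`z` is empty.")
  if (anyNA(z)) abort("`z` contains missing values.")
  which(2 * pnorm(-abs(z)) < alpha)
}

# Csorgo-Horvath asymptotic critical value for the sup likelihood-ratio
# statistic of a single change in d parameters of a normal sample:
#   P(a(log n) sqrt(LRT) - b_d(log n) <= x) -> exp(-2 exp(-x))
# with a(x) = sqrt(2 log x), b_d(x) = 2 log x + (d/2) log log x - log(Gamma(d/2)).
# Mean+variance change: d = 2.
meanvar_critical <- function(n, alpha) {
  x <- log(n)
  a <- sqrt(2 * log(x))
  b <- 2 * log(x) + log(log(x))         # d = 2, log Gamma(1) = 0
  q <- -log(-0.5 * log(1 - alpha))
  ((q + b) / a)^2
}

# LRT for the best single mean+variance split of z (normal model):
#   n log s2_full - n1 log s2_left - n2 log s2_right, maximised over splits
# leaving at least min_segment points on each side. Returns NULL or
# list(stat, split) where the new segment starts at split + 1.
best_meanvar_split <- function(z, min_segment) {
  n <- length(z)
  if (n < 2 * min_segment) return(NULL)
  cs <- cumsum(z)
  cs2 <- cumsum(z^2)
  j <- seq(min_segment, n - min_segment)
  n1 <- j
  n2 <- n - j
  s2_l <- pmax(cs2[j] / n1 - (cs[j] / n1)^2, 1e-12)
  s2_r <- pmax((cs2[n] - cs2[j]) / n2 - ((cs[n] - cs[j]) / n2)^2, 1e-12)
  s2_0 <- max(cs2[n] / n - (cs[n] / n)^2, 1e-12)
  stat <- n * log(s2_0) - n1 * log(s2_l) - n2 * log(s2_r)
  k <- which.max(stat)
  list(stat = stat[k], split = j[k])
}

#' Detect secretion-rate segments from standardized residuals
#'
#' Binary segmentation of the residual sequence under the normal
#' mean-and-variance changepoint model: at each step the best split is the
#' one maximising the likelihood-ratio statistic
#' \eqn{n\log\hat\sigma^2 - n_1\log\hat\sigma_1^2 - n_2\log\hat\sigma_2^2},
#' accepted when it exceeds the asymptotic critical value calibrated to the
#' significance level `alpha` (Csorgo-Horvath extreme-value limit for a
#' two-parameter change). Accepted segments are split recursively, with a
#' minimum segment length to keep segments on the weeks-to-months scale the
#' secretion-rate regimes live on. Sessions listed in `exclude` (e.g.
#' extreme-retention flags) are removed before segmentation so isolated
#' spikes cannot masquerade as regime changes; returned boundaries are
#' indices into the original sequence.
#'
#' @param z Standardized residuals, one per session.
#' @param alpha Significance level of each split test (default 0.05).
#' @param min_segment Minimum segment length in sessions (default 30,
#'   about two weeks of twice-daily milking).
#' @param exclude Integer indices removed before segmentation.
#' @return Sorted integer vector of boundary indices (first session of each
#'   new segment), empty when the sequence is homogeneous.
#' @examples
#' z <- c(rnorm(100), rnorm(100, mean = 1.5))
#' detect_beta_segments(z)
#' @export
detect_beta_segments <- function(z, alpha = 0.05, min_segment = 30,
                                 exclude = integer(0)) {
  if (length(z) == 0) abort("`z` is empty.")
  if (anyNA(z)) abort("`z` contains missing values.")
  keep <- setdiff(seq_along(z), exclude)
  zz <- z[keep]
  n <- length(zz)
  if (n < 2 * min_segment) return(integer(0))
  crit <- meanvar_critical(n, alpha)

  boundaries <- integer(0)
  recurse <- function(lo, hi) {
    sp <- best_meanvar_split(zz[lo:hi], min_segment)
    if (is.null(sp) || sp$stat <= crit) return(invisible(NULL))
    cut <- lo + sp$split - 1L          # last index of the left part
    boundaries <<- c(boundaries, cut)
    recurse(lo, cut)
    recurse(cut + 1L, hi)
  }
  recurse(1L, n)
  # boundary = first session of the new segment, in original indexing
  sort(keep[boundaries + 1L])
}
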
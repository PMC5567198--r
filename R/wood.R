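#' Wood's gamma lactation curve
#'
#' The classical empirical daily lactation curve
#' \eqn{Y(x) = a\, x^{b} e^{-c x}}: `a` scales the curve (kg/day), `b`
#' shapes the rise to peak and `c` the exponential decline. The peak falls
#' on day `b/c`.
#'
#' @param day Day(s) in milk, `> 0`.
#' @param a,b,c Wood parameters (`a > 0`, `c >= 0`).
#' @return Expected daily yield(s), kg.
#' @examples
#' wood_curve(1:5, a = 19.392, b = 0.1777, c = 0.00376)
#' @export
wood_curve <- function(day, a, b, c) {
  if (any(day <= 0)) abort("`day` must be > 0.")
  a * day^b * exp(-c * day)
}

#' Least-squares fit of Wood's model to daily yields
#'
#' Nonlinear least squares on the gamma curve, started from the
#' log-linearised regression \eqn{\log y = \log a + b\log x - c x}. Because
#' plain least squares assumes uncorrelated errors, the Box-Pierce test on
#' the fit residuals is reported: milk carryover between sessions induces
#' autocorrelation that this daily model cannot absorb, and a small
#' p-value warns that the least-squares confidence statements are
#' unreliable.
#'
#' @param daily A data frame with columns `day` and `yield` (>= 10 rows).
#' @return A `wood_fit` object with `$params` ([tidy()] for a tibble),
#'   `$fitted`, `$residuals` and `$box_pierce_pvalue`.
#' @examples
#' d <- tibble::tibble(day = 1:305,
#'                     yield = wood_curve(1:305, 19.4, 0.18, 0.0038))
#' f <- fit_wood(d)
#' tidy(f)
#' @export
fit_wood <- function(daily) {
  if (!all(c("day", "yield") %in% names(daily)))
    abort("`daily` needs columns `day` and `yield`.")
  if (nrow(daily) < 10) abort("need at least 10 daily observations.")
  pos <- daily$yield > 0
  start_lm <- lm(log(yield) ~ log(day) + day, data = daily[pos, ])
  start <- list(a = exp(unname(coef(start_lm)[1])),
                b = unname(coef(start_lm)[2]),
                c = -unname(coef(start_lm)[3]))
  fit <- tryCatch(
    minpack.lm::nlsLM(yield ~ a * day^b * exp(-c * day),
                      data = daily, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("Wood fit did not converge: ",
                                     conditionMessage(e))))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  res <- daily$yield - stats::fitted(fit)
  bp <- stats::Box.test(res, lag = min(20L, floor(nrow(daily) / 4)),
                        type = "Box-Pierce")
  structure(
    list(params = tibble::tibble(
           term = names(est),
           estimate = unname(est),
           std.error = unname(se),
           conf.low = unname(est - qnorm(0.975) * se),
           conf.high = unname(est + qnorm(0.975) * se)),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(res),
         daily = tibble::as_tibble(daily),
         box_pierce_pvalue = unname(bp$p.value),
         nls = fit),
    class = "wood_fit"
  )
}

#' @export
print.wood_fit <- function(x, ...) {
  cat("<wood_fit> ", nrow(x$daily), " days; Box-Pierce p = ",
      format.pval(x$box_pierce_pvalue), "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @rdname tidy.milking_fit
#' @method tidy wood_fit
#' @export
tidy.wood_fit <- function(x, ...) x$params

#' @rdname glance.milking_fit
#' @method glance wood_fit
#' @export
glance.wood_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$daily),
    sigma = sd(x$residuals),
    pearson_r = cor(x$daily$yield, x$fitted),
    box_pierce_pvalue = x$box_pierce_pvalue
  )
}

#' Peak and total statistics of a Wood curve
#'
#' Closed-form peak day `b/c`, peak yield \eqn{a (b/c)^b e^{-b}}, and total
#' production by daily summation of the curve over the lactation.
#'
#' @param params A `wood_fit`, or a named list/vector with `a`, `b`, `c`.
#' @param lactation_days Length of the lactation in days (summation range).
#' @return A one-row tibble: `peak_day`, `peak_yield`, `total_kg`.
#' @examples
#' wood_summaries(list(a = 19.392, b = 0.1777, c = 0.00376))
#' @export
wood_summaries <- function(params, lactation_days = 305) {
  if (inherits(params, "wood_fit"))
    params <- setNames(as.list(params$params$estimate), params$params$term)
  a <- params[["a"]]; b <- params[["b"]]; c <- params[["c"]]
  if (c <= 0 || b <= 0) abort("peak statistics need b > 0 and c > 0.")
  tibble::tibble(
    peak_day = b / c,
    peak_yield = a * (b / c)^b * exp(-b),
    total_kg = sum(wood_curve(seq_len(lactation_days), a, b, c))
  )
}
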
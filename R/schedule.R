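#' Build a milking schedule table
#'
#' A milking schedule is a tibble with one row per session and columns
#' `session` (1..K), `hours` (fractional hours since the first milking;
#' first session at 0) and `label` (`"morning"` or `"evening"`). Model time
#' is `t(k) = delta + hours(k)`, so the first interval spans lactation onset
#' to the first milking with an empty alveolar compartment.
#'
#' @param hours Strictly increasing numeric vector of session times in hours
#'   since the first milking (first element 0).
#' @param label Optional character vector of `"morning"`/`"evening"` flags;
#'   if `NULL`, labels alternate starting from `first_label`.
#' @param first_label Label of the first session when `label` is `NULL`.
#' @return A tibble with columns `session`, `hours`, `label` and the
#'   per-session interval `interval_h` (`NA` for the first session, whose
#'   interval is the onset offset `delta`).
#' @examples
#' milking_schedule(c(0, 10, 24, 34))
#' @export
milking_schedule <- function(hours, label = NULL, first_label = "morning") {
  if (length(hours) < 1L) abort("`hours` must contain at least one session.")
  if (hours[1] != 0) abort("`hours` must start at 0 (time of first milking).")
  if (is.unsorted(hours, strictly = TRUE))
    abort("`hours` must be strictly increasing (no duplicate session times).")
  K <- length(hours)
  if (is.null(label)) {
    first_label <- match.arg(first_label, c("morning", "evening"))
    label <- if (first_label == "morning") rep(c("morning", "evening"),
                                               length.out = K)
             else rep(c("evening", "morning"), length.out = K)
  } else {
    if (length(label) != K) abort("`label` must match `hours` in length.")
    bad <- setdiff(unique(label), c("morning", "evening"))
    if (length(bad)) abort("`label` entries must be 'morning' or 'evening'.")
  }
  tibble::tibble(
    session = seq_len(K),
    hours = as.numeric(hours),
    label = label,
    interval_h = c(NA_real_, diff(hours))
  )
}

#' Nominal twice-daily schedule
#'
#' Deterministic alternating schedule with fixed interval lengths: 14 hours
#' into each morning session and 10 hours into each evening session (the
#' conventional twice-daily milking routine).
#'
#' @param n_sessions Number of milking sessions.
#' @param intervals Named numeric vector of interval lengths (hours) by the
#'   label of the session the interval leads into.
#' @inheritParams milking_schedule
#' @return A schedule tibble (see [milking_schedule()]).
#' @examples
#' nominal_schedule(6)
#' @export
nominal_schedule <- function(n_sessions,
                             intervals = c(morning = 14, evening = 10),
                             first_label = "morning") {
  first_label <- match.arg(first_label, c("morning", "evening"))
  lab <- if (first_label == "morning") rep(c("morning", "evening"),
                                           length.out = n_sessions)
         else rep(c("evening", "morning"), length.out = n_sessions)
  gaps <- intervals[lab[-1]]
  milking_schedule(c(0, cumsum(gaps)), label = lab)
}

# internal: validate a data frame carrying schedule columns (and optionally
# observed yields); returns it with columns coerced
check_session_frame <- function(data, need_yield = FALSE) {
  req <- c("session", "hours", "label")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Build it with milking_schedule()/read_sessions()."))
  if (need_yield && !"yield" %in% names(data))
    abort("`data` must contain an observed `yield` column (kg per session).")
  if (is.unsorted(data$hours, strictly = TRUE))
    abort("session `hours` must be strictly increasing.")
  if (need_yield && any(data$yield < 0))
    abort("observed yields must be non-negative.")
  data
}
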
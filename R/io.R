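#' Read per-session milking records from CSV
#'
#' Expects one row per milking session with a `datetime` column (ISO 8601)
#' and either per-quarter yields `q1`..`q4` (kg, summed to the udder total)
#' or a single `total_kg` column. An optional `label` column flags
#' morning/evening sessions; otherwise a session before noon is a morning
#' session. Times are converted to fractional hours since the first session
#' by exact elapsed time.
#'
#' @param path Path to a CSV file.
#' @return A session tibble: `session`, `datetime`, `hours`, `label`,
#'   `yield`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("datetime,q1,q2,q3,q4",
#'              "2024-01-01 06:30,4,5,5,4",
#'              "2024-01-01 16:30,4,4,4,3"), f)
#' read_sessions(f)
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"datetime" %in% names(raw))
    abort("missing `datetime` column.")
  dt <- as.POSIXct(raw$datetime, tz = "UTC")
  if (anyNA(dt)) {
    bad <- which(is.na(dt))[1] + 1L   # +1 for the header line
    abort(paste0("unparseable datetime at line ", bad, "."))
  }
  if (anyNA(raw)) {
    bad <- which(!stats::complete.cases(raw))[1] + 1L
    abort(paste0("missing value at line ", bad, "."))
  }
  d <- diff(as.numeric(dt))
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 2L
    abort(paste0("non-increasing datetime at line ", bad,
                 " (sessions must be strictly ordered)."))
  }
  quarters <- intersect(c("q1", "q2", "q3", "q4"), names(raw))
  if (length(quarters) == 4L) {
    qsum <- rowSums(raw[quarters])
    if ("total_kg" %in% names(raw) &&
        any(abs(raw$total_kg - qsum) > 1e-6))
      abort("`total_kg` disagrees with the quarter sum.")
    yield <- qsum
  } else if ("total_kg" %in% names(raw)) {
    yield <- raw$total_kg
  } else {
    abort("need either quarter columns q1..q4 or a `total_kg` column.")
  }
  if (any(yield < 0)) {
    bad <- which(yield < 0)[1] + 1L
    abort(paste0("negative yield at line ", bad, "."))
  }
  hours <- as.numeric(difftime(dt, dt[1], units = "hours"))
  label <- if ("label" %in% names(raw)) raw$label
           else ifelse(as.integer(format(dt, "%H")) < 12, "morning", "evening")
  bad_lab <- setdiff(unique(label), c("morning", "evening"))
  if (length(bad_lab))
    abort("`label` entries must be 'morning' or 'evening'.")
  tibble::tibble(session = seq_along(hours), datetime = dt,
                 hours = hours, label = label, yield = as.numeric(yield))
}

#' Write per-session milking records to CSV
#'
#' Inverse of [read_sessions()]: writes `datetime` (constructed from `hours`
#' and `origin` when no `datetime` column is present), `label` and
#' `total_kg`. A read of the written file reproduces the session table.
#'
#' @param data A session tibble with `hours`, `label`, `yield`.
#' @param path Output CSV path.
#' @param origin Timestamp of the first session used when `data` carries no
#'   `datetime` column.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(data, path,
                           origin = as.POSIXct("2024-01-01 06:00:00",
                                               tz = "UTC")) {
  data <- check_session_frame(data, need_yield = TRUE)
  dt <- if ("datetime" %in% names(data)) data$datetime
        else origin + data$hours * 3600
  out <- tibble::tibble(
    datetime = format(dt, "%Y-%m-%dT%H:%M:%OS2", tz = "UTC"),
    label = data$label,
    total_kg = data$yield
  )
  readr::write_csv(out, path)
  invisible(path)
}
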
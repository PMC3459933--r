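#' Construct a CGM glucose trace
#'
#' A `glucose_trace` is a regularly sampled interstitial glucose series for
#' one subject: a start time, a fixed sampling interval (5 min for the CGMS
#' devices this package targets), an ordered numeric vector of glucose
#' concentrations and a unit tag. Missing samples are `NA` in `values` and
#' mirrored in `missing_mask`.
#'
#' @param values Numeric vector of glucose concentrations (length >= 2).
#'   `NA` marks a missing sample.
#' @param start Start time of the first sample, a `POSIXct` or a string
#'   parseable as one. Timestamps are timezone-naive and interpreted in the
#'   trace's own clock (stored as UTC).
#' @param interval Sampling period in minutes (default 5).
#' @param unit `"mmol_per_l"` or `"mg_per_dl"`.
#' @param subject_id Opaque subject identifier.
#'
#' @return An object of class `glucose_trace`.
#' @export
#' @examples
#' tr <- glucose_trace(c(5.2, 6.1, 7.0), "2024-03-01 00:00:00")
#' trace_times(tr)
glucose_trace <- function(values, start, interval = 5,
                          unit = c("mmol_per_l", "mg_per_dl"),
                          subject_id = "subject") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2) stop("glucose_trace: need at least 2 samples")
  if (!is.numeric(interval) || length(interval) != 1 || interval <= 0)
    stop("glucose_trace: interval must be a single positive number of minutes")
  if (inherits(start, "POSIXct")) {
    start <- as.POSIXct(format(start, "%Y-%m-%d %H:%M:%S"), tz = "UTC")
  } else {
    start <- as.POSIXct(start, tz = "UTC")
  }
  if (is.na(start)) stop("glucose_trace: unparseable start time")
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop(sprintf("glucose_trace: non-positive glucose at sample(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  structure(
    list(subject_id = subject_id, start = start, interval = interval,
         values = values, unit = unit, missing_mask = is.na(values)),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf(
    "<glucose_trace> subject %s: %d samples @ %g min from %s [%s], %.1f%% complete\n",
    x$subject_id, length(x$values), x$interval,
    format(x$start, "%Y-%m-%d %H:%M"), x$unit, 100 * trace_completeness(x)))
  invisible(x)
}

#' Sample timestamps of a trace
#' @param trace A `glucose_trace`.
#' @return `POSIXct` vector, one element per sample.
#' @export
trace_times <- function(trace) {
  trace$start + (seq_along(trace$values) - 1) * trace$interval * 60
}

#' Fraction of non-missing samples
#' @param trace A `glucose_trace`.
#' @return Completeness in `[0, 1]`.
#' @export
trace_completeness <- function(trace) mean(!trace$missing_mask)

#' Convert a trace between mmol/l and mg/dl
#'
#' Conversion is exact: mg/dl = mmol/l x 18.016.
#'
#' @param trace A `glucose_trace`.
#' @param to Target unit.
#' @return The converted trace (unchanged if already in `to`).
#' @export
convert_units <- function(trace, to = c("mmol_per_l", "mg_per_dl")) {
  to <- match.arg(to)
  if (trace$unit == to) return(trace)
  f <- if (to == "mg_per_dl") MGDL_PER_MMOL else 1 / MGDL_PER_MMOL
  trace$values <- trace$values * f
  trace$unit <- to
  trace
}

# non-missing values, optionally in a fixed unit
trace_values <- function(trace, unit = NULL, drop_na = TRUE) {
  if (!is.null(unit)) trace <- convert_units(trace, unit)
  v <- trace$values
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Select the 48-h analysis window of a CGM recording
#'
#' Clinical CGM protocols discard the run-in period: analysis uses the
#' `window_hours` of recording starting from the first midnight *strictly
#' after* the device was started (a recording started exactly at midnight
#' uses the following midnight). At a 5-min interval a 48-h window holds
#' exactly 576 samples.
#'
#' @param trace A `glucose_trace`, typically a raw 72-h recording.
#' @param window_hours Window length in hours (default 48).
#' @return A `glucose_trace` starting at that midnight with exactly
#'   `window_hours * 60 / interval` samples.
#' @export
select_analysis_window <- function(trace, window_hours = 48) {
  stopifnot(inherits(trace, "glucose_trace"))
  times <- trace_times(trace)
  day0 <- as.Date(trace$start, tz = "UTC")
  window_start <- as.POSIXct(paste(format(day0 + 1), "00:00:00"), tz = "UTC")
  n_need <- as.integer(round(window_hours * 60 / trace$interval))
  i0 <- match(TRUE, times >= window_start)
  n_have <- if (is.na(i0)) 0L else length(trace$values) - i0 + 1L
  if (n_have < n_need) {
    stop(sprintf(
      paste0("window not coverable: need %d samples (%g h) from %s, ",
             "recording provides %d (short by %d samples, %.1f h)"),
      n_need, window_hours, format(window_start, "%Y-%m-%d %H:%M"),
      n_have, n_need - n_have, (n_need - n_have) * trace$interval / 60))
  }
  idx <- seq(i0, i0 + n_need - 1L)
  glucose_trace(trace$values[idx], start = times[i0],
                interval = trace$interval, unit = trace$unit,
                subject_id = trace$subject_id)
}
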
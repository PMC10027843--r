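#' Uniformly sampled physiological channel
#'
#' `time_series()` is the universal currency of the pipeline: one uniformly
#' sampled channel with a sampling rate, a start offset on the shared session
#' clock, physical units and a label. Sample `i` (1-based) sits at time
#' `t0 + (i - 1) / fs` seconds.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample on the session clock, in seconds.
#' @param units Physical units of the samples (e.g. `"mmHg"`, `"%"`,
#'   `"uM"`, `"OD"`, `"s.d.u."`).
#' @param label Channel name (e.g. `"ABP"`, `"TSI"`).
#' @return An object of class `time_series`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 1.44 * (0:599) / 10), fs = 10, label = "ABP")
#' ts
time_series <- function(values, fs, t0 = 0, units = "", label = "") {
  if (!is.numeric(values) || length(values) == 0) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(values = as.double(values), fs = as.double(fs), t0 = as.double(t0),
         units = units, label = label),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %s: %d samples @ %g Hz, t = [%.3f, %.3f] s%s\n",
    if (nzchar(x$label)) x$label else "(unnamed)",
    length(x$values), x$fs, x$t0, ts_end(x),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a series
#' @param ts A [time_series()].
#' @return Numeric vector of sample times (s) on the session clock.
#' @export
ts_time <- function(ts) ts$t0 + (seq_along(ts$values) - 1) / ts$fs

#' Time of the last sample (s)
#' @param ts A [time_series()].
#' @export
ts_end <- function(ts) ts$t0 + (length(ts$values) - 1) / ts$fs

#' Extract a time window
#'
#' Returns the samples with `from <= t < to` (half-open, with a half-sample
#' tolerance so grid round-off never drops an end point).
#'
#' @param ts A [time_series()].
#' @param from,to Window bounds in seconds on the session clock.
#' @param require_full Error if the window is not fully covered by the
#'   recording (default `FALSE`: truncate silently).
#' @return A [time_series()] restricted to the window.
#' @export
ts_window <- function(ts, from, to, require_full = FALSE) {
  if (to <= from) stop("empty window: `to` must exceed `from`", call. = FALSE)
  eps <- 0.5 / ts$fs
  if (require_full && (from < ts$t0 - eps || to > ts_end(ts) + 1 / ts$fs + eps)) {
    stop(sprintf(
      "window [%g, %g] s outside recording [%g, %g] s of channel '%s'",
      from, to, ts$t0, ts_end(ts), ts$label), call. = FALSE)
  }
  t <- ts_time(ts)
  idx <- which(t >= from - eps & t < to - eps)
  if (length(idx) == 0) {
    stop(sprintf("window [%g, %g] s contains no samples of channel '%s'",
                 from, to, ts$label), call. = FALSE)
  }
  time_series(ts$values[idx], ts$fs, t0 = t[idx[1]],
              units = ts$units, label = ts$label)
}

#' Mean of a series over a time window
#' @inheritParams ts_window
#' @export
ts_window_mean <- function(ts, from, to) mean(ts_window(ts, from, to)$values)

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = ts_time(x), value = x$values)
}

#' Convert a series to a tibble
#' @param ts A [time_series()].
#' @return A tibble with columns `time_s` and `value`.
#' @export
ts_tibble <- function(ts) tibble::tibble(time_s = ts_time(ts), value = ts$values)
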
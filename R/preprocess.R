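#' Resample a channel to a target rate
#'
#' Upsampling uses linear interpolation; downsampling first applies a
#' zero-phase low-pass (4th-order Butterworth at 0.45 x target rate, run
#' forward and backward so the timing of downstream detection statistics is
#' preserved) and then interpolates onto the target grid. The output spans
#' the same interval and starts at the same `t0`.
#'
#' @param ts A [time_series()].
#' @param target Target rate (Hz, > 0).
#' @return A [time_series()] at `target` Hz.
#' @export
resample_ts <- function(ts, target) {
  if (!is.numeric(target) || target <= 0) {
    stop("`target` rate must be positive", call. = FALSE)
  }
  if (isTRUE(all.equal(ts$fs, target))) return(ts)
  x <- ts$values
  if (target < ts$fs) {
    w <- 0.45 * target / (ts$fs / 2)
    bf <- signal::butter(4, w, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  t_old <- ts_time(ts)
  t_new <- seq(ts$t0, ts_end(ts), by = 1 / target)
  v <- stats::approx(t_old, x, xout = t_new, rule = 2)$y
  time_series(v, target, t0 = ts$t0, units = ts$units, label = ts$label)
}

#' Align two streams via shared artifact patterns
#'
#' Estimates the clock offset between independently recorded streams by
#' maximizing the normalized cross-correlation of the traces'
#' high-frequency *envelopes* over integer-sample lags within `max_lag`.
#' Each trace is high-pass filtered (default 0.4 Hz, zero-phase; above
#' typical ventilation rates so a shared respiratory oscillation cannot
#' produce peaks one breath period off), rectified, and smoothed into an
#' energy envelope. Correlating envelopes rather than waveforms matters
#' when both streams carry the same quasi-periodic cardiac component:
#' waveform correlation peaks wherever *beats* align (every pulse period),
#' whereas the envelope is flat under steady pulsation and localized at
#' the shared motion artifacts (and at the pulse-amplitude collapse), so
#' the peak sits at the true offset. The returned offset is the shift to
#' *add to the time base of `b`* to bring its content into coincidence
#' with `a`; alignment is inverse-consistent within one sample.
#'
#' @param a,b [time_series()] at a common rate (`b` is resampled to `a`'s
#'   rate if needed).
#' @param max_lag Search half-range (s).
#' @param highpass High-pass corner (Hz); `NULL` to skip filtering.
#' @param min_cor Confidence floor for the correlation peak; below it the
#'   alignment is declared ambiguous and an error is thrown.
#' @return The offset (s), with attribute `"peak_cor"`.
#' @export
align_streams <- function(a, b, max_lag = 10, highpass = 0.4,
                          min_cor = 0.2) {
  if (!isTRUE(all.equal(a$fs, b$fs))) b <- resample_ts(b, a$fs)
  fs <- a$fs
  envelope <- function(ts) {
    x <- ts$values
    if (is.null(highpass)) return(x)
    bf <- signal::butter(2, highpass / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
    # rectified energy envelope, smoothed hard enough (0.25 Hz) that the two
    # lobes of a rectified biphasic transient merge into one symmetric bump
    lp <- signal::butter(2, min(0.25, fs / 2 * 0.8) / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, abs(x))
    # blank the filter edge transients: both arrays carry them at their
    # own boundaries, which would otherwise correlate at index lag 0
    ne <- min(length(x), ceiling(5 * fs))
    x[seq_len(ne)] <- 0
    x[seq.int(length(x) - ne + 1L, length(x))] <- 0
    x
  }
  # localization uses only the largest envelope excursions (the artifact
  # bursts): steady pulsation gives a flat envelope that would dilute the
  # peak. Confidence is evaluated on the full envelope, whose correlation
  # has well-behaved statistics (sparse clipped traces can correlate highly
  # at arbitrary lags by chance).
  ea <- envelope(a)
  eb <- envelope(b)
  xa <- pmax(ea - stats::quantile(ea, 0.995), 0)
  xb <- pmax(eb - stats::quantile(eb, 0.995), 0)
  lag_cor <- function(u, v, k) {
    if (k >= 0) {
      n <- min(length(u), length(v) - k)
      if (n < fs) return(NA_real_)
      suppressWarnings(stats::cor(u[1:n], v[(1 + k):(n + k)]))
    } else {
      n <- min(length(u) + k, length(v))
      if (n < fs) return(NA_real_)
      suppressWarnings(stats::cor(u[(1 - k):(n - k)], v[1:n]))
    }
  }
  lags <- seq(-round(max_lag * fs), round(max_lag * fs))
  cc <- vapply(lags, function(k) lag_cor(xa, xb, k), numeric(1))
  best <- which.max(cc)
  if (!length(best) || is.na(cc[best]) || cc[best] < min_cor) {
    stop(sprintf(
      "alignment ambiguous: envelope correlation peak %.3f below floor %.3f",
      if (!length(best) || is.na(cc[best])) 0 else cc[best], min_cor),
      call. = FALSE)
  }
  # refinement by event matching: locate the individual artifact bursts in
  # each envelope (sub-sample parabolic centres), pair them up under the
  # coarse lag, and take the median of the per-event time differences --
  # the automated version of matching artifact patterns by eye
  peak_centres <- function(env, n_max = 10L) {
    e <- env
    th <- 0.35 * max(e)
    out <- numeric(0)
    guard <- round(3 * fs)
    while (length(out) < n_max) {
      i <- which.max(e)
      if (!length(i) || e[i] <= th || e[i] <= 0) break
      d <- 0
      if (i > 1 && i < length(env)) {
        den <- env[i - 1] - 2 * env[i] + env[i + 1]
        if (abs(den) > 1e-12) {
          d <- max(min(0.5 * (env[i - 1] - env[i + 1]) / den, 0.5), -0.5)
        }
      }
      out <- c(out, i + d)
      e[max(1, i - guard):min(length(e), i + guard)] <- -Inf
    }
    out
  }
  k0 <- lags[best]
  pa <- peak_centres(ea)
  pb <- peak_centres(eb)
  fine <- k0
  if (length(pa) && length(pb)) {
    diffs <- vapply(pa, function(ci) {
      j <- which.min(abs(pb - (ci + k0)))
      pb[j] - ci
    }, numeric(1))
    matched <- diffs[abs(diffs - k0) <= fs]  # within 1 s of the coarse lag
    if (length(matched)) fine <- stats::median(matched)
  }
  # content of b at index i+k matches a at index i: b's content lags by k/fs
  # on its own clock, so its time base must be shifted by -k/fs (plus any
  # difference in recorded start times) to coincide with a
  offset <- (a$t0 - b$t0) - fine / fs
  attr(offset, "peak_cor") <- cc[best]
  offset
}

#' Z-score a channel against a reference window
#'
#' `(x - mean_ref) / sd_ref`, with mean and SD taken over the reference
#' window, so the output is in standard deviation units (s.d.u.) and the
#' reference window of the output has mean 0 and SD 1.
#'
#' @param ts A [time_series()].
#' @param reference Numeric `c(from, to)` (s), inside the recording.
#' @return A [time_series()] in s.d.u.
#' @export
zscore_ts <- function(ts, reference) {
  ref <- ts_window(ts, reference[1], reference[2], require_full = TRUE)
  m <- mean(ref$values)
  s <- stats::sd(ref$values)
  if (!is.finite(s) || s <= .Machine$double.eps^0.5) {
    stop(sprintf(
      "degenerate baseline: channel '%s' has zero variance over the reference window",
      ts$label), call. = FALSE)
  }
  time_series((ts$values - m) / s, ts$fs, ts$t0,
              units = "s.d.u.", label = ts$label)
}

#' Assemble an aligned analysis session
#'
#' Resamples every channel to a common rate, applies a per-channel
#' alignment offset, and cuts the standard analysis window of
#' `[marker - pre, marker + post]` (default 10 min before and 5 min after
#' the infusion marker). Channels that do not cover the full window are
#' kept, truncated, with a warning (post-euthanasia captures may be short).
#'
#' @param channels Named list of [time_series()].
#' @param marker Infusion marker time (s) on the session clock.
#' @param target_fs Common rate (Hz).
#' @param offsets Named numeric vector of alignment offsets (s) to add to
#'   the time base of the corresponding channels (e.g. from
#'   [align_streams()]); unnamed channels get 0.
#' @param pre,post Window extent (s) before/after the marker.
#' @return A list of class `aligned_session` with elements `channels`,
#'   `marker`, `window`, `offsets`, `target_fs`.
#' @export
aligned_session <- function(channels, marker, target_fs = 10,
                            offsets = NULL, pre = 600, post = 300) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  win <- c(marker - pre, marker + post)
  out <- lapply(names(channels), function(nm) {
    ts <- channels[[nm]]
    off <- if (!is.null(offsets) && nm %in% names(offsets)) offsets[[nm]] else 0
    ts$t0 <- ts$t0 + off
    ts <- resample_ts(ts, target_fs)
    if (ts$t0 > win[1] + 0.5 / target_fs ||
        ts_end(ts) < win[2] - 1 / target_fs - 0.5 / target_fs) {
      warning(sprintf(
        "channel '%s' covers [%.1f, %.1f] s; analysis window [%.1f, %.1f] s truncated",
        nm, ts$t0, ts_end(ts), win[1], win[2]), call. = FALSE)
    }
    ts_window(ts, max(win[1], ts$t0), min(win[2], ts_end(ts)) + 1 / target_fs)
  })
  names(out) <- names(channels)
  structure(
    list(channels = out, marker = marker, window = win,
         offsets = offsets, target_fs = target_fs),
    class = "aligned_session"
  )
}

#' @export
print.aligned_session <- function(x, ...) {
  cat(sprintf("<aligned_session> %d channels @ %g Hz, marker %g s, window [%g, %g] s\n",
              length(x$channels), x$target_fs, x$marker,
              x$window[1], x$window[2]))
  invisible(x)
}
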
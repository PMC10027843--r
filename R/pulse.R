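#' STFT analysis specification
#'
#' Parameters of the short-time Fourier transform used for pulse-rate and
#' pulse-amplitude estimation: 10-Hz input, 528-sample FFT frames and 24%
#' overlap, i.e. a hop of `round(528 * 0.76) = 401` samples and a frequency
#' bin width of `fs / nfft` (about 0.019 Hz). The default physiological
#' pulse band is 0.5-4 Hz. The taper is a Hann window, fixed here so
#' results are reproducible.
#'
#' @param fs Sampling rate (Hz).
#' @param nfft Frame/FFT length (samples, >= 2).
#' @param overlap Fractional overlap between frames, in `[0, 1)`.
#' @param window_fn Taper name (`"hann"` or `"rectangular"`).
#' @param band Pulse band `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @return An object of class `stft_spec`.
#' @export
stft_spec <- function(fs = 10, nfft = 528, overlap = 0.24,
                      window_fn = c("hann", "rectangular"),
                      band = c(0.5, 4.0)) {
  window_fn <- match.arg(window_fn)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (nfft < 2) stop("`nfft` must be >= 2", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("`band` must lie within (0, fs/2)", call. = FALSE)
  }
  structure(
    list(fs = fs, nfft = as.integer(nfft), overlap = overlap,
         hop = max(1L, as.integer(round(nfft * (1 - overlap)))),
         window_fn = window_fn, band = band),
    class = "stft_spec"
  )
}

.stft_taper <- function(spec) {
  n <- spec$nfft
  switch(spec$window_fn,
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         rectangular = rep(1, n))
}

#' Spectrogram of a z-scored channel
#'
#' Frames of `nfft` samples hop by `nfft * (1 - overlap)` samples (partial
#' trailing frames are dropped); each frame is tapered and Fourier
#' transformed. The one-sided power is amplitude-calibrated: a full-frame
#' sinusoid of amplitude `a` lands (up to leakage) in one bin with power
#' `a^2 / 2` -- its time-domain power -- so powers are comparable across
#' channels once the inputs are z-scored to unit variance.
#'
#' @param ts A [time_series()] at `spec$fs`, normally in s.d.u. (see
#'   [zscore_ts()]).
#' @param spec An [stft_spec()].
#' @return A list of class `spectrogram`: `power` (bins x frames), `freq`
#'   (Hz), `time` (frame centres, s), `spec`, `taper_norm`.
#' @export
spectrogram_ts <- function(ts, spec = stft_spec()) {
  if (!isTRUE(all.equal(ts$fs, spec$fs))) {
    stop(sprintf("trace rate %g Hz does not match spec fs %g Hz", ts$fs, spec$fs),
         call. = FALSE)
  }
  n <- length(ts)
  if (n < spec$nfft) {
    stop(sprintf("trace too short for one %d-sample frame", spec$nfft),
         call. = FALSE)
  }
  starts <- seq(1L, n - spec$nfft + 1L, by = spec$hop)
  w <- .stft_taper(spec)
  U <- sum(w)
  frames <- vapply(starts, function(s0) {
    ts$values[s0:(s0 + spec$nfft - 1)] * w
  }, numeric(spec$nfft))
  X <- stats::mvfft(frames)
  nb <- floor(spec$nfft / 2) + 1L
  amp <- 2 * Mod(X[1:nb, , drop = FALSE]) / U
  amp[1, ] <- amp[1, ] / 2                       # DC is not doubled
  if (spec$nfft %% 2 == 0) amp[nb, ] <- amp[nb, ] / 2   # nor Nyquist
  power <- amp^2 / 2
  structure(
    list(power = power,
         freq = (0:(nb - 1)) * spec$fs / spec$nfft,
         time = ts$t0 + (starts - 1 + (spec$nfft - 1) / 2) / spec$fs,
         spec = spec, taper_norm = U),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, df = %.4f Hz\n",
              nrow(x$power), ncol(x$power), x$freq[2] - x$freq[1]))
  invisible(x)
}

.band_idx <- function(spg, band) {
  which(spg$freq >= band[1] & spg$freq <= band[2])
}

# frame-wise silence floor: `margin_db` above the median broadband power
# (DC excluded). For ~200 one-sided bins of white noise the max/median
# ratio of chi-squared(2) periodogram powers is ~9.5 dB, so the 12-dB
# default keeps pure-noise frames silent while real tones clear it easily.
.silence_floor <- function(spg, margin_db = 12) {
  med <- apply(spg$power[-1, , drop = FALSE], 2, stats::median)
  pmax(med * 10^(margin_db / 10), 1e-12)
}

#' Pulse rate from a spectrogram
#'
#' Per frame, the dominant in-band frequency, or 0 (pulseless) when the
#' in-band peak power does not exceed the frame's silence floor. Reported
#' as mean over frames with a 95% confidence half-width (Student t; 0 when
#' only one frame is available).
#'
#' @param spg A [spectrogram_ts()] result.
#' @param band Pulse band (Hz); defaults to the spec's.
#' @param silence_margin_db Silence floor margin above the frame's median
#'   broadband power (dB).
#' @param window_label Label carried into the output row.
#' @return A one-row tibble: `window_label`, `rate_mean`, `rate_ci95`,
#'   `n_frames`, `n_silent`, plus the per-frame rates as attribute
#'   `"frame_rates"`.
#' @export
pulse_rate <- function(spg, band = spg$spec$band, silence_margin_db = 12,
                       window_label = "") {
  idx <- .band_idx(spg, band)
  floor_p <- .silence_floor(spg, silence_margin_db)
  rates <- vapply(seq_len(ncol(spg$power)), function(j) {
    p <- spg$power[idx, j]
    i <- which.max(p)
    if (p[i] <= floor_p[j]) 0 else spg$freq[idx[i]]
  }, numeric(1))
  n <- length(rates)
  ci <- 0
  if (n > 1 && stats::sd(rates) > 0) {
    ci <- stats::qt(0.975, n - 1) * stats::sd(rates) / sqrt(n)
  }
  out <- tibble::tibble(window_label = window_label, rate_mean = mean(rates),
                        rate_ci95 = ci, n_frames = n,
                        n_silent = sum(rates == 0))
  attr(out, "frame_rates") <- rates
  out
}

#' Pulse amplitude (dB) from a spectrogram
#'
#' `10 log10` of the mean in-band peak power across frames. Because the
#' spectrogram's power scale is amplitude-calibrated and inputs are
#' z-scored, the implicit reference is the unit variance of the normalized
#' input -- the only reference under which cross-channel comparison is
#' meaningful. An all-silent matrix yields `-Inf` with attribute
#' `no_pulse = TRUE`.
#'
#' @inheritParams pulse_rate
#' @return A numeric scalar (dB) with attributes `reference` and
#'   `no_pulse`.
#' @export
pulse_amplitude <- function(spg, band = spg$spec$band) {
  idx <- .band_idx(spg, band)
  peaks <- apply(spg$power[idx, , drop = FALSE], 2, max)
  m <- mean(peaks)
  out <- if (m <= 0) -Inf else 10 * log10(m)
  attr(out, "reference") <- "unit variance of z-scored input"
  attr(out, "no_pulse") <- !is.finite(out)
  out
}

#' Three-window pulse analysis of a session
#'
#' Replicates the standard three 60-s analysis windows -- baseline (ending
#' at the marker), the interval immediately following the infusion, and a
#' post-euthanasia window starting `post_offset` s after the marker
#' (default 240 s, i.e. the last minute of the 5-min capture) -- and
#' reports the pulse rate and amplitude of both the pressure- and the
#' oxyhemoglobin-derived channel in each.
#'
#' @param abp_z,o2hb_z Z-scored [time_series()] at `spec$fs`.
#' @param marker Infusion marker time (s).
#' @param spec An [stft_spec()].
#' @param post_offset Start of the post-euthanasia window relative to the
#'   marker (s).
#' @param silence_margin_db Passed to [pulse_rate()].
#' @return A tibble: `window`, `channel`, `rate_hz`, `rate_ci95`,
#'   `amp_db`, `n_frames`.
#' @export
three_window_analysis <- function(abp_z, o2hb_z, marker, spec = stft_spec(),
                                  post_offset = 240,
                                  silence_margin_db = 12) {
  windows <- list(pre = c(marker - 60, marker),
                  during = c(marker, marker + 60),
                  post = c(marker + post_offset, marker + post_offset + 60))
  chans <- list(ABP = abp_z, O2Hb = o2hb_z)
  purrr::map_dfr(names(windows), function(wn) {
    purrr::map_dfr(names(chans), function(cn) {
      seg <- ts_window(chans[[cn]], windows[[wn]][1], windows[[wn]][2],
                       require_full = TRUE)
      spg <- spectrogram_ts(seg, spec)
      pr <- pulse_rate(spg, silence_margin_db = silence_margin_db,
                       window_label = wn)
      tibble::tibble(window = wn, channel = cn, rate_hz = pr$rate_mean,
                     rate_ci95 = pr$rate_ci95,
                     amp_db = as.numeric(pulse_amplitude(spg)),
                     n_frames = pr$n_frames)
    })
  })
}
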
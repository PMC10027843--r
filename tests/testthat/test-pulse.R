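spec10 <- stft_spec()

test_that("spec invariants and the documented hop", {
  expect_equal(spec10$hop, 401L)   # round(528 * 0.76)
  expect_error(stft_spec(overlap = 1), "overlap")
  expect_error(stft_spec(band = c(0, 6)), "band")
  expect_error(stft_spec(nfft = 1), "nfft")
})

test_that("stationary tones are recovered within one frequency bin", {
  for (f in c(0.7, 1.08, 1.44, 2.25, 3.6)) {
    tone <- make_tone(f, dur = 180)
    spg <- spectrogram_ts(zscore_ts(tone, c(0, 60)), spec10)
    peaks <- spg$freq[apply(spg$power, 2, which.max)]
    expect_true(all(abs(peaks - f) <= 10 / 528 + 1e-9))
    pr <- pulse_rate(spg)
    expect_lt(abs(pr$rate_mean - f), 10 / 528 + 1e-9)
  }
})

test_that("zero input gives an all-zero matrix and a zero rate", {
  z <- time_series(rep(0, 600), 10)
  spg <- spectrogram_ts(z, spec10)
  expect_true(all(spg$power == 0))
  pr <- pulse_rate(spg)
  expect_equal(pr$rate_mean, 0)
  expect_equal(pr$rate_ci95, 0)
  amp <- pulse_amplitude(spg)
  expect_identical(as.numeric(amp), -Inf)
  expect_true(attr(amp, "no_pulse"))
})

test_that("the power scale satisfies Parseval's identity per frame", {
  set.seed(20)
  ts <- time_series(rnorm(1500), 10)
  spg <- spectrogram_ts(ts, spec10)
  w <- nirsarrest:::.stft_taper(spec10)
  U <- sum(w)
  n <- spec10$nfft
  for (j in seq_len(ncol(spg$power))) {
    seg <- ts$values[((j - 1) * spec10$hop + 1):((j - 1) * spec10$hop + n)]
    # reconstruct |X_k|^2 from the amplitude-calibrated one-sided powers:
    # interior bins were doubled once and carry the tone-power half
    p <- spg$power[, j]
    nb <- length(p)
    xk2 <- p * U^2 / 2
    xk2[1] <- 2 * p[1] * U^2
    if (n %% 2 == 0) xk2[nb] <- 2 * p[nb] * U^2
    two_sided <- xk2[1] + (if (n %% 2 == 0) xk2[nb] else 0) +
      2 * sum(xk2[2:(nb - 1)])
    expect_equal(two_sided / n, sum((w * seg)^2), tolerance = 1e-8)
  }
})

test_that("spectrogram magnitudes agree with an independent STFT", {
  set.seed(21)
  ts <- time_series(rnorm(1400), 10)
  spg <- spectrogram_ts(ts, spec10)
  w <- nirsarrest:::.stft_taper(spec10)
  for (j in seq_len(ncol(spg$power))) {
    seg <- ts$values[((j - 1) * spec10$hop + 1):((j - 1) * spec10$hop + 528)]
    X <- fft(seg * w)[seq_len(265)]
    amp <- 2 * Mod(X) / sum(w); amp[1] <- amp[1] / 2; amp[265] <- amp[265] / 2
    expect_equal(spg$power[, j], amp^2 / 2, tolerance = 1e-10)
  }
})

test_that("a chirp produces monotonically increasing frame rates", {
  fs <- 10; dur <- 300
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  f0 <- 1.3; f1 <- 1.9
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  ts <- time_series(sin(phase), fs)
  spg <- spectrogram_ts(ts, spec10)
  rates <- attr(pulse_rate(spg), "frame_rates")
  expect_gt(length(rates), 3)
  expect_true(all(diff(rates) > 0))
})

test_that("amplitude halves by ~6.02 dB and ignores DC offsets", {
  tone <- make_tone(1.44, dur = 120, amp = 1)
  half <- make_tone(1.44, dur = 120, amp = 0.5)
  a1 <- pulse_amplitude(spectrogram_ts(tone, spec10))
  a2 <- pulse_amplitude(spectrogram_ts(half, spec10))
  expect_equal(as.numeric(a1 - a2), 20 * log10(2), tolerance = 0.01)
  shifted <- time_series(tone$values + 5, 10)
  a3 <- pulse_amplitude(spectrogram_ts(shifted, spec10))
  expect_equal(as.numeric(a1), as.numeric(a3), tolerance = 0.05)
  # equal waveforms give equal amplitude
  expect_equal(as.numeric(a1),
               as.numeric(pulse_amplitude(spectrogram_ts(tone, spec10))))
})

test_that("pulseless noise is reported as rate 0 +/- 0", {
  set.seed(22)
  noise <- time_series(rnorm(1800), 10)
  pr <- pulse_rate(spectrogram_ts(zscore_ts(noise, c(0, 60)), spec10))
  expect_equal(pr$rate_mean, 0)
  expect_equal(pr$rate_ci95, 0)
  expect_equal(pr$n_silent, pr$n_frames)
})

test_that("three-window analysis reproduces the physiology of one animal", {
  cfg <- animal_config(seed = 30, residual_cardiac_duration = 120)
  sim <- simulate_animal(cfg)
  an <- analyze_animal(sim, align = FALSE)
  p <- an$pulse
  pre <- p[p$window == "pre", ]
  # both channels report the programmed heart rate within one bin
  expect_lt(abs(pre$rate_hz[pre$channel == "ABP"] - cfg$hr_baseline), 10 / 528)
  expect_lt(abs(pre$rate_hz[pre$channel == "O2Hb"] - cfg$hr_baseline), 10 / 528)
  expect_lt(abs(pre$rate_hz[1] - pre$rate_hz[2]), 10 / 528 + 1e-9)
  # tachycardia raises the during-euthanasia rate
  dur <- p[p$window == "during", ]
  expect_gt(dur$rate_hz[dur$channel == "ABP"],
            pre$rate_hz[pre$channel == "ABP"])
  expect_lt(abs(dur$rate_hz[1] - dur$rate_hz[2]), 10 / 528 + 1e-9)
  # residual pulsation has ended by the post window: both channels silent
  post <- p[p$window == "post", ]
  expect_equal(post$rate_hz, c(0, 0))
  expect_equal(post$rate_ci95, c(0, 0))
  # pressure-derived pulse amplitudes exceed the optically derived ones
  expect_gt(pre$amp_db[pre$channel == "ABP"],
            pre$amp_db[pre$channel == "O2Hb"])
  expect_gt(dur$amp_db[dur$channel == "ABP"],
            dur$amp_db[dur$channel == "O2Hb"])
  # amplitudes collapse from baseline to euthanasia in both channels
  expect_lt(dur$amp_db[dur$channel == "ABP"], pre$amp_db[pre$channel == "ABP"])
  expect_lt(dur$amp_db[dur$channel == "O2Hb"],
            pre$amp_db[pre$channel == "O2Hb"])
})

test_that("traces shorter than one frame are rejected", {
  expect_error(spectrogram_ts(time_series(rnorm(100), 10), spec10),
               "too short")
})
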
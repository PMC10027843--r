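# Independent oracles and small constructors used across the suite.

# Brute-force first-crossing scan: literal per-sample loop over the post-
# marker samples, independent of the run-length implementation in the
# package.
brute_force_latency <- function(ts, marker, k = 2, baseline_dur = 60,
                                direction = "falling") {
  t <- ts_time(ts)
  base <- ts$values[t >= marker - baseline_dur & t < marker]
  thr <- if (direction == "falling") {
    mean(base) - k * stats::sd(base)
  } else {
    mean(base) + k * stats::sd(base)
  }
  for (i in which(t >= marker)) {
    hit <- if (direction == "falling") ts$values[i] < thr else ts$values[i] > thr
    if (hit) return(t[i] - marker)
  }
  NA_real_
}

# pure sinusoid channel
make_tone <- function(freq, fs = 10, dur = 60, amp = 1, t0 = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  time_series(amp * sin(2 * pi * freq * t), fs, t0 = t0, label = "tone")
}

# a quiet config: no noise, no respiration, no artifacts, no tachycardia
quiet_config <- function(...) {
  animal_config(
    noise_sd = list(abp = 0, tsi = 0, od = 0, po2 = 0),
    resp = list(rate_hz = 0.18, abp = 0, tsi = 0, po2 = 0),
    artifact_schedule = NULL,
    tachycardia = NULL,
    ...
  )
}
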
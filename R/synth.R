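# --- shared latent physiology -------------------------------------------------
#
# All channels of one animal are deterministic functions of the config plus
# channel-specific Gaussian noise; the cardiac phase, pulse envelope and decay
# trajectories below are evaluated on each stream's own sampling grid so the
# underlying "heart" is shared across independently clocked streams.

# instantaneous pulse rate (Hz), incl. the optional post-infusion tachycardia
.hr_instant <- function(cfg, t) {
  hr <- rep(cfg$hr_baseline, length(t))
  tk <- cfg$tachycardia
  if (!is.null(tk) && tk$peak > 0) {
    u <- t - cfg$arrest_time
    in_t <- u > 0 & u < tk$duration
    hr[in_t] <- hr[in_t] + tk$peak * sin(pi * u[in_t] / tk$duration)
  }
  hr
}

# cumulative cardiac phase (beats) on a uniform grid
.cardiac_phase <- function(cfg, t, fs) cumsum(.hr_instant(cfg, t)) / fs

# rectified-sinusoid beat template in [0, 1]; mean over a beat is 2/pi
.beat_shape <- function(phase) abs(sin(pi * phase))

.tau_map <- function(cfg) {
  if (!is.null(cfg$tau_map)) return(cfg$tau_map)
  map0 <- cfg$sys_baseline / 3 + 2 * cfg$dia_baseline / 3
  (52.6 - cfg$map_lag) / log(map0 / 5)
}

# mean-pressure trajectory (mmHg): flat, then exponential collapse toward
# the configured floor (0 by default; the post-arrest static filling
# pressure when nonzero)
.map_target <- function(cfg, t) {
  map0 <- cfg$sys_baseline / 3 + 2 * cfg$dia_baseline / 3
  onset <- cfg$arrest_time + cfg$map_lag
  u <- pmax(t - onset, 0)
  cfg$map_floor + (map0 - cfg$map_floor) * exp(-u / .tau_map(cfg))
}

# pulse-amplitude envelope in [0, 1]: collapses with tau_map but is floored at
# the residual fraction until residual activity ends, then tapers out (5-s tc)
.pulse_envelope <- function(cfg, t) {
  onset <- cfg$arrest_time + cfg$map_lag
  u <- pmax(t - onset, 0)
  env <- exp(-u / .tau_map(cfg))
  res_end <- cfg$arrest_time + cfg$residual_cardiac_duration
  floor_amp <- cfg$residual_amp_frac *
    ifelse(t <= res_end, 1, exp(-(t - res_end) / 5))
  pmax(env, floor_amp)
}

# saturation trajectory (%): drop depth calibrated so the mean over the last
# 10 s of the 5-min post window equals cfg$tsi_drop
.tsi_target <- function(cfg, t) {
  onset <- cfg$arrest_time + cfg$tsi_lag
  u <- seq(290 - cfg$tsi_lag, 300 - cfg$tsi_lag - 0.1, by = 0.1)
  denom <- mean(1 - exp(-u / cfg$tau_tsi))
  d_inf <- cfg$tsi_drop / denom
  drop <- d_inf * (1 - exp(-pmax(t - onset, 0) / cfg$tau_tsi))
  cfg$tsi_baseline - drop
}

.po2_target <- function(cfg, t) {
  onset <- cfg$arrest_time + cfg$po2_lag
  u <- pmax(t - onset, 0)
  cfg$po2_floor + (cfg$po2_baseline - cfg$po2_floor) * exp(-u / cfg$tau_po2)
}

# respiratory (ventilator) modulation: smooth sinusoid at resp$rate_hz with a
# channel-specific amplitude and phase; the dominant source of baseline
# variability in every channel. Transmission of ventilation pressure into
# every channel requires circulation, so the amplitude collapses with the
# pulse envelope after arrest.
.resp_wave <- function(cfg, t, amp, phase) {
  amp * .pulse_envelope(cfg, t) * sin(2 * pi * cfg$resp$rate_hz * t + phase)
}

# effective baseline SD per analysis channel: respiratory variance (amp^2/2)
# plus white measurement noise. The sliding-extrema MAP estimator attenuates
# white pressure noise; 0.35 is the empirical attenuation of the rolling
# max/min of N(0,1) over a 1-s window at 100 Hz.
.effective_sd <- function(cfg, channel) {
  r <- cfg$resp
  switch(channel,
         MAP = sqrt(r$abp^2 / 2 + (0.35 * cfg$noise_sd$abp)^2),
         TSI = sqrt(r$tsi^2 / 2 + cfg$noise_sd$tsi^2),
         PO2 = sqrt(r$po2^2 / 2 + cfg$noise_sd$po2^2))
}

# unit biphasic transient (derivative-of-Gaussian, peak amplitude 1)
.artifact_shape <- function(t, center, width) {
  x <- (t - center) / width
  x * exp(0.5 - x^2 / 2)
}

.artifact_sum <- function(cfg, t, scale) {
  out <- numeric(length(t))
  sch <- cfg$artifact_schedule
  if (is.null(sch) || nrow(sch) == 0) return(out)
  for (i in seq_len(nrow(sch))) {
    out <- out + scale * sch$amplitude[i] *
      .artifact_shape(t, sch$time[i], sch$width[i])
  }
  out
}

# --- channel simulators -------------------------------------------------------

#' Simulate the arterial blood pressure waveform
#'
#' Pre-arrest, the pressure oscillates between the diastolic and systolic
#' baselines at the baseline pulse rate with a rectified-sinusoid beat
#' template; after the infusion marker (plus a circulation lag) both the
#' mean pressure and the pulsatile envelope decay exponentially toward a
#' near-zero floor, with low-amplitude residual pulsation persisting for
#' `residual_cardiac_duration`. The ventilator's respiratory modulation
#' (scaled by the pulse envelope), Gaussian measurement noise and the
#' shared motion artifacts are added last. Bit-identical for identical
#' config.
#'
#' @param config An [animal_config()].
#' @param fs Sampling rate, 10 or 100 Hz (invasive pressure was recorded at
#'   either depending on protocol).
#' @param post_duration Capture length after the marker (s).
#' @return A [time_series()] in mmHg starting at t = 0.
#' @export
simulate_abp <- function(config, fs = 100, post_duration = 300) {
  if (!fs %in% c(10, 100)) {
    stop("invalid `fs`: arterial pressure is sampled at 10 or 100 Hz",
         call. = FALSE)
  }
  if (post_duration <= 0) {
    stop("invalid `post_duration`: must be positive", call. = FALSE)
  }
  t <- seq(0, config$arrest_time + post_duration, by = 1 / fs)
  phase <- .cardiac_phase(config, t, fs)
  s <- .beat_shape(phase)
  map_t <- .map_target(config, t)
  pp <- (config$sys_baseline - config$dia_baseline) *
    .pulse_envelope(config, t)
  # dia_t + pp * s has window min dia_t, max sys_t and MAP exactly map_t
  p <- (map_t - pp / 3) + pp * s
  noisy <- withr::with_seed(config$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    p + .resp_wave(config, t, config$resp$abp, phase) +
      stats::rnorm(length(t), sd = config$noise_sd$abp)
  })
  noisy <- noisy + .artifact_sum(config, t, scale = 60)
  time_series(noisy, fs, t0 = 0, units = "mmHg", label = "ABP")
}

#' Simulate the multi-distance dual-wavelength optical recording
#'
#' Generates latent oxy-/deoxyhemoglobin trajectories whose saturation
#' equals `tsi_baseline` pre-arrest and decays with `tau_tsi` afterwards
#' (drop depth calibrated to `tsi_drop`), adds a cardiac pulsatile
#' component on oxyhemoglobin whose amplitude tracks the arterial pulse
#' envelope, converts everything to attenuation with
#' [forward_attenuation()] (the same model the analysis inverts), and adds
#' per-channel optical-density noise plus the shared motion artifacts.
#'
#' The optical stream runs on its own clock: if `stream_offset_nirs` is
#' non-zero the recorded content lags the returned timestamps by that
#' amount, emulating independently started acquisition software.
#'
#' @param config An [animal_config()].
#' @param geometry An [optical_geometry()].
#' @param fs Sampling rate (Hz).
#' @param post_duration Capture length after the marker (s).
#' @return An [optical_recording()] with t0 = 0 on the optical clock.
#' @export
simulate_optics <- function(config, geometry = optical_geometry(),
                            fs = 10, post_duration = 300) {
  if (post_duration <= 0) {
    stop("invalid `post_duration`: must be positive", call. = FALSE)
  }
  # pad the capture by the clock offset (plus a margin for one-sample
  # alignment jitter) so the analysis window on the session clock stays
  # covered after alignment
  pad <- abs(config$stream_offset_nirs) + 2
  t_rec <- seq(-pad, config$arrest_time + post_duration + pad, by = 1 / fs)
  t <- t_rec + config$stream_offset_nirs  # true physiological time
  tsi_clean <- .tsi_target(config, t)
  if (any(tsi_clean <= 0 | tsi_clean >= 100)) {
    stop("saturation trajectory leaves (0, 100); check tsi_baseline/tsi_drop",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    phase <- stats::runif(1, 0, 2 * pi)
    tsi_sig <- tsi_clean + .resp_wave(config, t, config$resp$tsi, phase) +
      stats::rnorm(length(t), sd = config$noise_sd$tsi)
    o2hb <- time_series(tsi_sig / 100 * config$thb_total, fs, t_rec[1],
                        "uM", "O2Hb")
    hhb <- time_series(config$thb_total - o2hb$values, fs, t_rec[1],
                       "uM", "HHb")
    pulse <- config$pulse_amp_o2hb * .pulse_envelope(config, t) *
      (.beat_shape(.cardiac_phase(config, t, fs)) - 2 / pi)
    rec <- forward_attenuation(o2hb, hhb, geometry, o2hb_pulse = pulse)
    nch <- prod(dim(rec$attenuation)[2:3])
    rec$attenuation <- rec$attenuation +
      array(stats::rnorm(length(t) * nch, sd = config$noise_sd$od),
            dim = dim(rec$attenuation))
  })
  art <- .artifact_sum(config, t, scale = 0.05)
  rec$attenuation <- rec$attenuation + array(art, dim = dim(rec$attenuation))
  rec
}

#' Simulate the tissue PO2 channel
#'
#' A 1-Hz trace, flat at `po2_baseline` until the marker plus `po2_lag`
#' (oxygen release from hemoglobin buffers the dissolved-oxygen pool, so
#' this channel is the slowest to respond), then exponential decay with
#' `tau_po2` toward `po2_floor` (~0.5 mmHg), plus Gaussian noise.
#'
#' @param config An [animal_config()].
#' @param post_duration Capture length after the marker (s).
#' @return A [time_series()] in mmHg at 1 Hz.
#' @export
simulate_po2 <- function(config, post_duration = 300) {
  if (post_duration <= 0) {
    stop("invalid `post_duration`: must be positive", call. = FALSE)
  }
  t <- seq(0, config$arrest_time + post_duration, by = 1)
  clean <- .po2_target(config, t)
  noisy <- withr::with_seed(config$seed + 2L, {
    phase <- stats::runif(1, 0, 2 * pi)
    clean + .resp_wave(config, t, config$resp$po2, phase) +
      stats::rnorm(length(t), sd = config$noise_sd$po2)
  })
  time_series(noisy, 1, t0 = 0, units = "mmHg", label = "PO2")
}

# noiseless channel trajectories for ground truth: the deterministic decay
# plus the (equally deterministic) respiratory modulation, whose phase is
# the first draw of each channel's seeded RNG stream -- i.e. the signal the
# detector sees minus measurement noise
.truth_trace <- function(cfg, channel, t) {
  phase_of <- function(seed) {
    withr::with_seed(seed, stats::runif(1, 0, 2 * pi))
  }
  switch(channel,
         MAP = .map_target(cfg, t) +
           .resp_wave(cfg, t, cfg$resp$abp, phase_of(cfg$seed)),
         TSI = .tsi_target(cfg, t) +
           .resp_wave(cfg, t, cfg$resp$tsi, phase_of(cfg$seed + 1L)),
         PO2 = .po2_target(cfg, t) +
           .resp_wave(cfg, t, cfg$resp$po2, phase_of(cfg$seed + 2L)))
}

# first grid sample strictly beyond baseline -/+ k * sd, as latency from the
# marker; the per-channel ground truth against which detection is scored
.truth_crossing <- function(values, fs, t0, marker, baseline, sd,
                            k = 2, direction = "falling") {
  t <- t0 + (seq_along(values) - 1) / fs
  thr <- if (direction == "falling") baseline - k * sd else baseline + k * sd
  post <- which(t >= marker)
  hit <- if (direction == "falling") values[post] < thr else values[post] > thr
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  t[post[i]] - marker
}

#' Simulate one full experiment with ground truth
#'
#' Runs [simulate_abp()], [simulate_optics()] and [simulate_po2()] from one
#' config and records, per channel, the programmed baselines and the
#' noiseless first-crossing times of the 2-SD detection threshold (scanned
#' on each channel's own grid), plus the true pulse-rate trajectory.
#'
#' @param config An [animal_config()].
#' @param abp_fs ABP sampling rate (10 or 100 Hz).
#' @param geometry An [optical_geometry()].
#' @param post_duration Capture length after the marker (s).
#' @return A list of class `arrest_sim` with elements `config`, `marker`,
#'   `abp`, `optics`, `po2` and `truth` (`crossings` tibble, `pulse`
#'   tibble).
#' @export
simulate_animal <- function(config, abp_fs = 100,
                            geometry = optical_geometry(),
                            post_duration = 300) {
  abp <- simulate_abp(config, fs = abp_fs, post_duration = post_duration)
  optics <- simulate_optics(config, geometry, post_duration = post_duration)
  po2 <- simulate_po2(config, post_duration = post_duration)
  marker <- config$arrest_time

  t10 <- seq(0, marker + post_duration, by = 0.1)
  map0 <- config$sys_baseline / 3 + 2 * config$dia_baseline / 3
  cross <- tibble::tibble(
    animal = config$animal_id,
    channel = c("MAP", "TSI", "PO2"),
    baseline_true = c(map0, config$tsi_baseline, config$po2_baseline),
    noise_sd = c(.effective_sd(config, "MAP"), .effective_sd(config, "TSI"),
                 .effective_sd(config, "PO2")),
    crossing_s = c(
      .truth_crossing(.truth_trace(config, "MAP", t10), 10, 0, marker, map0,
                      .effective_sd(config, "MAP")),
      .truth_crossing(.truth_trace(config, "TSI", t10), 10, 0, marker,
                      config$tsi_baseline, .effective_sd(config, "TSI")),
      .truth_crossing(.truth_trace(config, "PO2",
                                   seq(0, marker + post_duration)),
                      1, 0, marker, config$po2_baseline,
                      .effective_sd(config, "PO2"))
    )
  )
  t1 <- seq(0, marker + post_duration, by = 1)
  env <- .pulse_envelope(config, t1)
  pulse <- tibble::tibble(
    animal = config$animal_id, time_s = t1,
    rate_hz = ifelse(env > 0.01, .hr_instant(config, t1), 0),
    envelope = env
  )
  structure(
    list(config = config, marker = marker, abp = abp, optics = optics,
         po2 = po2, truth = list(crossings = cross, pulse = pulse)),
    class = "arrest_sim"
  )
}

#' @export
print.arrest_sim <- function(x, ...) {
  cat(sprintf("<arrest_sim> %s: marker at %g s, ABP @ %g Hz, optics @ %g Hz\n",
              x$config$animal_id, x$marker, x$abp$fs, x$optics$fs))
  invisible(x)
}

# default sampler: draws per-animal configs around the reference cohort's
# means/SDs (clipped to physiological ranges)
.default_sampler <- function(i) {
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  map0 <- clip(stats::rnorm(1, 78.7, 17.7), 45, 130)
  pp <- 40
  animal_config(
    animal_id = sprintf("sim%02d", i),
    hr_baseline = clip(stats::rnorm(1, 1.69, 0.45), 0.7, 3.2),
    sys_baseline = map0 + 2 * pp / 3,
    dia_baseline = map0 - pp / 3,
    tsi_baseline = clip(stats::rnorm(1, 67.2, 6.5), 45, 90),
    po2_baseline = clip(stats::rnorm(1, 38.7, 19.9), 8, 80),
    map_lag = clip(stats::rnorm(1, 10, 4.5), 2, 25),
    tsi_lag = abs(stats::rnorm(1, 0, 1.8)),
    po2_lag = clip(stats::rnorm(1, 24, 9), 5, 60),
    tachycardia = if (stats::runif(1) < 0.75) {
      list(peak = stats::runif(1, 0.3, 0.8), duration = 60)
    },
    residual_cardiac_duration = stats::runif(1, 330, 960),
    seed = 0L  # overwritten by the cohort driver
  )
}

#' Simulate a cohort of euthanasia experiments
#'
#' Draws `n` per-animal configurations (from `config_sampler`, or from a
#' built-in sampler centred on the reference cohort's means and SDs),
#' simulates every animal, and assembles the combined ground truth. With
#' `preset = "reference"` the eight configs of [reference_configs()] are
#' used instead, so per-animal baselines equal the printed reference
#' values. Fully reproducible from `seed`.
#'
#' @param n_animals Number of animals (>= 1); ignored for the reference
#'   preset (always 8).
#' @param config_sampler Optional `function(i)` returning an
#'   [animal_config()]; called under the cohort's seeded RNG.
#' @param seed Integer cohort seed.
#' @param preset `"sampled"` (default) or `"reference"`.
#' @param ... Passed to [simulate_animal()] (e.g. `abp_fs`).
#' @return A list of class `arrest_cohort`: `animals` (list of
#'   `arrest_sim`), `configs`, and `truth` (row-bound crossing tibble).
#' @export
simulate_cohort <- function(n_animals, config_sampler = NULL, seed = 1L,
                            preset = c("sampled", "reference"), ...) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    configs <- reference_configs(seed = seed)
  } else {
    if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
    sampler <- config_sampler %||% .default_sampler
    configs <- withr::with_seed(seed, {
      seeds <- sample.int(.Machine$integer.max - 10L, n_animals)
      lapply(seq_len(n_animals), function(i) {
        cfg <- sampler(i)
        # a sampler may pin per-animal seeds itself; 0 means "assign one"
        if (identical(cfg$seed, 0L)) cfg$seed <- seeds[i]
        cfg
      })
    })
  }
  animals <- lapply(configs, simulate_animal, ...)
  truth <- dplyr::bind_rows(lapply(animals, function(a) a$truth$crossings))
  structure(list(animals = animals, configs = configs, truth = truth),
            class = "arrest_cohort")
}

#' @export
print.arrest_cohort <- function(x, ...) {
  cat(sprintf("<arrest_cohort> %d animals\n", length(x$animals)))
  invisible(x)
}
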
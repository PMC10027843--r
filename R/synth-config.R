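#' Configuration of one synthetic euthanasia experiment
#'
#' Bundles every physiological and instrumental parameter of one simulated
#' animal. Defaults describe a typical anesthetized miniature pig and are
#' calibrated so that the standard analysis pipeline reproduces the
#' published cohort-level behaviour of the porcine euthanasia experiment the
#' generator emulates: the mean arterial pressure (MAP) collapses below
#' 5 mmHg about 52.6 s after the infusion marker, the noiseless 2-SD
#' first-change latencies land near 10.4 s (MAP), 12.0 s (TSI) and 25.0 s
#' (tissue PO2), and the saturation drop over the 5-min post window matches
#' the configured `tsi_drop`.
#'
#' @param animal_id Label.
#' @param hr_baseline Baseline pulse rate (Hz), in (0.5, 4).
#' @param sys_baseline,dia_baseline Systolic/diastolic pressure (mmHg),
#'   `0 < dia < sys`.
#' @param tsi_baseline Baseline tissue saturation index (%), in (0, 100).
#' @param po2_baseline Baseline tissue PO2 (mmHg).
#' @param arrest_time Time (s) of the pentobarbital infusion marker.
#' @param dose_note Free-text dose annotation (metadata only).
#' @param tau_map,tau_tsi,tau_po2 Exponential decay constants (s) of the
#'   post-arrest collapse of MAP, TSI and PO2. `tau_map = NULL` (default)
#'   derives the constant from the 52.6-s collapse calibration:
#'   `(52.6 - map_lag) / ln(MAP0 / 5)`.
#' @param map_lag,tsi_lag,po2_lag Delay (s) between the infusion marker and
#'   the onset of each channel's decay (circulatory transport plus, for PO2,
#'   the oxygen-buffering of hemoglobin). All >= 0.
#' @param tsi_drop Programmed saturation drop (%) realized as the mean of the
#'   last 10 s of the 5-min post window relative to baseline.
#' @param map_floor Asymptote of the MAP decay (mmHg). 0 by default (the
#'   near-zero collapse the calibration example assumes); set it to the
#'   post-arrest mean systemic filling pressure to emulate recordings in
#'   which arterial pressure settles at a nonzero static level.
#' @param po2_floor Asymptote of the PO2 decay (mmHg).
#' @param tachycardia `NULL`, or `list(peak = dHz, duration = s)` describing
#'   a transient half-sine pulse-rate increase starting at the marker.
#' @param residual_cardiac_duration Time (s) after the marker during which
#'   low-amplitude pulsation persists (clinically dead heart still showing
#'   electrical/mechanical activity).
#' @param residual_amp_frac Amplitude of that residual pulsation as a
#'   fraction of the baseline pulse amplitude.
#' @param thb_total Total tissue hemoglobin concentration (uM) used by the
#'   optics forward model.
#' @param pulse_amp_o2hb Baseline amplitude (uM) of the cardiac pulsatile
#'   component riding on oxyhemoglobin.
#' @param noise_sd Named list of additive Gaussian white measurement-noise
#'   SDs: `abp` (mmHg), `tsi` (saturation %, applied to the latent
#'   saturation), `od` (optical density per attenuation channel), `po2`
#'   (mmHg).
#' @param resp Respiratory (ventilator) modulation: `rate_hz` plus
#'   per-channel peak amplitudes `abp` (mmHg), `tsi` (%), `po2` (mmHg).
#'   In mechanically ventilated animals this smooth oscillation dominates
#'   the baseline variability of every channel, which is what makes a
#'   strict single-sample 2-SD rule usable: the bounded sinusoid never
#'   reaches 2 baseline SDs on its own, while heavy-tailed white noise of
#'   the same total SD would false-trigger within seconds.
#' @param artifact_schedule Data frame with columns `time` (s), `amplitude`
#'   (relative units) and `width` (s): shared biphasic motion transients
#'   injected into both the pressure and the optical streams.
#' @param stream_offset_nirs Clock offset (s) of the independently recorded
#'   optical stream relative to the pressure/PO2 stream; the content of the
#'   optical recording lags its own timestamps by this amount, which
#'   [align_streams()] can recover from the shared artifacts.
#' @param seed Integer seed; every simulation from the same config is
#'   bit-identical.
#' @return An object of class `animal_config`.
#' @export
animal_config <- function(animal_id = "sim",
                          hr_baseline = 1.69,
                          sys_baseline = 105.39,
                          dia_baseline = 65.39,
                          tsi_baseline = 67.20,
                          po2_baseline = 38.75,
                          arrest_time = 600,
                          dose_note = "120 mg/kg over 5 s",
                          tau_map = NULL,
                          tau_tsi = 120,
                          tau_po2 = 25,
                          map_lag = 9.5,
                          tsi_lag = 7,
                          po2_lag = 24,
                          tsi_drop = 14.50,
                          map_floor = 0,
                          po2_floor = 0.5,
                          tachycardia = list(peak = 0.5, duration = 60),
                          residual_cardiac_duration = 480,
                          residual_amp_frac = 0.10,
                          thb_total = 60,
                          pulse_amp_o2hb = 0.4,
                          noise_sd = list(abp = 0.8, tsi = 0.10,
                                          od = 2e-4, po2 = 0.1),
                          resp = list(rate_hz = 0.18, abp = 4.5,
                                      tsi = 1.05, po2 = 0.69),
                          artifact_schedule = default_artifacts(),
                          stream_offset_nirs = 0,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "animal_config")
  validate_animal_config(cfg)
  cfg
}

#' Default shared motion-artifact schedule
#'
#' Five biphasic transients during the baseline period, which is what makes
#' offline alignment of the independently clocked streams possible.
#' @return A tibble with columns `time`, `amplitude`, `width`.
#' @export
default_artifacts <- function() {
  tibble::tibble(time = c(60, 150, 300, 420, 540),
                 amplitude = c(0.8, 1, 1.2, 1, 0.9),
                 width = rep(0.5, 5))
}

validate_animal_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk(cfg$hr_baseline > 0.5 && cfg$hr_baseline < 4.0, "hr_baseline",
      "pulse rate must lie in (0.5, 4.0) Hz")
  chk(cfg$dia_baseline > 0 && cfg$dia_baseline < cfg$sys_baseline,
      "dia_baseline", "need 0 < diastolic < systolic")
  chk(cfg$tsi_baseline > 0 && cfg$tsi_baseline < 100, "tsi_baseline",
      "saturation must lie in (0, 100) %")
  chk(cfg$po2_baseline > 0, "po2_baseline", "must be positive")
  chk(cfg$arrest_time > 0, "arrest_time", "must be positive")
  for (f in c("tau_tsi", "tau_po2")) {
    chk(cfg[[f]] > 0, f, "decay constant must be positive")
  }
  if (!is.null(cfg$tau_map)) chk(cfg$tau_map > 0, "tau_map", "must be positive")
  for (f in c("map_lag", "tsi_lag", "po2_lag")) {
    chk(cfg[[f]] >= 0, f, "onset delay must be >= 0")
  }
  chk(cfg$tsi_drop > 0 && cfg$tsi_drop < cfg$tsi_baseline, "tsi_drop",
      "must be positive and smaller than the baseline saturation")
  if (!is.null(cfg$tachycardia)) {
    chk(cfg$tachycardia$peak >= 0 && cfg$tachycardia$duration > 0,
        "tachycardia", "need peak >= 0 and duration > 0")
  }
  chk(cfg$residual_cardiac_duration >= 0, "residual_cardiac_duration",
      "must be >= 0")
  chk(cfg$map_floor >= 0 && cfg$map_floor < cfg$dia_baseline, "map_floor",
      "must be in [0, diastolic)")
  invisible(cfg)
}

#' @export
print.animal_config <- function(x, ...) {
  cat(sprintf(
    "<animal_config> %s: HR %.2f Hz, ABP %.1f/%.1f mmHg, TSI %.1f%%, PO2 %.1f mmHg, marker %g s\n",
    x$animal_id, x$hr_baseline, x$sys_baseline, x$dia_baseline,
    x$tsi_baseline, x$po2_baseline, x$arrest_time))
  invisible(x)
}

#' Per-animal reference values of the porcine euthanasia cohort
#'
#' The published per-animal baseline and post-euthanasia values (baseline
#' averaged over 60 s pre-infusion; euthanasia value averaged over the last
#' 10 s of the 5-min post window) for carotid MAP, spinal-cord PO2 and
#' hindlimb TSI in eight animals. MAP is missing for one animal (degraded
#' signal quality) and PO2 for two (protocol changes), giving n = 7 / 6 / 8
#' per channel. These printed values are the worked-example input of
#' [cohort_table()] and seed the `"reference"` preset of
#' [simulate_cohort()].
#'
#' @return A tibble with one row per animal and columns
#'   `animal`, `map_baseline`, `map_eut`, `po2_baseline`, `po2_eut`,
#'   `tsi_baseline`, `tsi_eut`.
#' @export
reference_cohort <- function() {
  tibble::tibble(
    animal = 1:8,
    map_baseline = c(109.08, 67.32, 75.69, 65.71, 95.94, 60.21, 77.09, NA),
    map_eut      = c(31.02, 11.55, 10.86, 15.53, 11.15, 7.76, 10.38, NA),
    po2_baseline = c(15.74, 25.26, 32.40, 72.91, 45.96, NA, NA, 40.26),
    po2_eut      = c(0.87, 0.79, 0.48, 0.38, 0.32, NA, NA, 0.70),
    tsi_baseline = c(56.35, 61.52, 65.26, 70.96, 73.50, 69.55, 64.40, 76.08),
    tsi_eut      = c(49.27, 45.00, 51.36, 52.61, 60.34, 55.43, 45.01, 62.63)
  )
}

#' Reference per-animal pulse rates from the three-window STFT analysis
#'
#' Published pulse rates (Hz, mean over STFT frames +/- 95% CI half-width)
#' for the arterial-blood-pressure and NIRS-oxyhemoglobin channels in the
#' three 60-s analysis windows. The post-euthanasia row is 0 +/- 0 in every
#' animal (pulseless by the amplitude floor of the published analysis).
#'
#' @return A tibble with columns `window`, `channel`, `animal`, `rate_hz`,
#'   `rate_ci95`.
#' @export
reference_pulse_rates <- function() {
  pre_abp <- c(1.44, 1.51, 1.56, 2.67, 1.33, 1.08, 1.64, 2.25)
  pre_abp_ci <- c(0.14, 0.02, 0.14, 0.01, 0.02, 0.02, 0.02, 0.00)
  pre_nirs <- pre_abp
  pre_nirs_ci <- c(0.02, 0.03, 0.14, 0.01, 0.03, 0.02, 0.02, 0.01)
  dur_abp <- c(1.47, 1.47, 1.46, 2.18, 1.94, 1.92, 1.98, 1.59)
  dur_abp_ci <- c(0.21, 0.15, 0.54, 0.39, 0.49, 0.39, 0.26, 0.77)
  dur_nirs <- c(1.45, 1.46, 1.37, 2.18, 1.98, 1.92, 1.96, 1.74)
  dur_nirs_ci <- c(0.19, 0.14, 0.44, 0.38, 0.38, 0.44, 0.28, 0.54)
  zeros <- rep(0, 8)
  tibble::tibble(
    window = rep(c("pre", "during", "post"), each = 16),
    channel = rep(rep(c("ABP", "O2Hb"), each = 8), times = 3),
    animal = rep(1:8, times = 6),
    rate_hz = c(pre_abp, pre_nirs, dur_abp, dur_nirs, zeros, zeros),
    rate_ci95 = c(pre_abp_ci, pre_nirs_ci, dur_abp_ci, dur_nirs_ci,
                  zeros, zeros)
  )
}

#' Animal configurations matching the reference cohort
#'
#' Builds eight [animal_config()]s whose baselines equal the printed
#' per-animal values of [reference_cohort()] and whose heart rates equal the
#' pre-euthanasia rates of [reference_pulse_rates()]. Missing channels are
#' still simulated (from cohort-mean baselines) but flagged so that cohort
#' summaries exclude them with the published n per channel. Systolic and
#' diastolic pressures are decomposed from MAP with a fixed 40-mmHg pulse
#' pressure (`sys = MAP + 2 PP / 3`, `dia = MAP - PP / 3`).
#'
#' @param seed Base seed; animal i gets `seed + i`.
#' @return A list of eight `animal_config` objects, each carrying logical
#'   attributes `map_present` and `po2_present`.
#' @export
reference_configs <- function(seed = 101L) {
  ref <- reference_cohort()
  pr <- reference_pulse_rates()
  hr <- pr$rate_hz[pr$window == "pre" & pr$channel == "ABP"]
  pp <- 40
  lapply(1:8, function(i) {
    map0 <- ref$map_baseline[i]
    if (is.na(map0)) map0 <- mean(ref$map_baseline, na.rm = TRUE)
    po2 <- ref$po2_baseline[i]
    if (is.na(po2)) po2 <- mean(ref$po2_baseline, na.rm = TRUE)
    cfg <- animal_config(
      animal_id = paste0("ref", i),
      hr_baseline = hr[i],
      sys_baseline = map0 + 2 * pp / 3,
      dia_baseline = map0 - pp / 3,
      tsi_baseline = ref$tsi_baseline[i],
      po2_baseline = po2,
      tsi_drop = ref$tsi_baseline[i] - ref$tsi_eut[i],
      map_floor = if (is.na(ref$map_eut[i])) {
        mean(ref$map_eut, na.rm = TRUE)
      } else ref$map_eut[i],
      seed = seed + i
    )
    attr(cfg, "map_present") <- !is.na(ref$map_baseline[i])
    attr(cfg, "po2_present") <- !is.na(ref$po2_baseline[i])
    cfg
  })
}
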
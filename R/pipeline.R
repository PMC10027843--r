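#' End-to-end analysis of one recorded experiment
#'
#' Runs the full pipeline on one animal's raw recordings: MAP derivation
#' from the pressure waveform, SRS saturation and MBLL oxyhemoglobin from
#' the optical recording, artifact-based stream alignment, resampling to a
#' common 10-Hz session, baseline-vs-euthanasia summaries, 2-SD
#' first-change detection per channel, and the three-window STFT pulse
#' analysis on the z-scored pressure and oxyhemoglobin channels.
#'
#' @param sim An `arrest_sim` (or any list with elements `abp`, `optics`,
#'   `po2`, `marker`, `config`).
#' @param geometry An [optical_geometry()].
#' @param align Align the optical stream to the pressure stream via shared
#'   artifacts (default `TRUE`); with `FALSE` the streams are assumed
#'   synchronous.
#' @param max_lag Alignment search half-range (s).
#' @param k,persistence Detection parameters (see [first_change_time()]).
#' @param spec An [stft_spec()] for the pulse analysis.
#' @return A list of class `arrest_analysis`: `animal`, `offset_nirs`,
#'   `summaries`, `detections`, `pulse`, `session`.
#' @export
analyze_animal <- function(sim, geometry = optical_geometry(), align = TRUE,
                           max_lag = 10, k = 2, persistence = 1,
                           spec = stft_spec()) {
  marker <- sim$marker
  cfg <- sim$config
  map10 <- map_trace(sim$abp)
  tsi <- srs_tsi(sim$optics, geometry)
  opt_end <- sim$optics$t0 + (dim(sim$optics$attenuation)[1] - 1) / sim$optics$fs
  o2hb <- mbll_delta(sim$optics, geometry,
                     reference = c(sim$optics$t0, opt_end))$o2hb

  offset <- 0
  if (align) {
    # align on the pre-marker segment only: the shared motion artifacts live
    # there, and the arrest transition (tachycardia, amplitude collapse)
    # would otherwise compete with them in the envelope correlation
    abp10 <- ts_window(resample_ts(sim$abp, 10), sim$abp$t0, marker)
    o2hb_pre <- ts_window(o2hb, o2hb$t0, marker)
    offset <- as.numeric(align_streams(abp10, o2hb_pre, max_lag = max_lag))
  }

  session <- aligned_session(
    list(ABP = resample_ts(sim$abp, 10), MAP = map10, TSI = tsi,
         O2Hb = o2hb, PO2 = sim$po2),
    marker = marker, target_fs = 10,
    offsets = c(TSI = offset, O2Hb = offset)
  )

  id <- cfg$animal_id
  summaries <- dplyr::bind_rows(
    pre_post_summary(session$channels$MAP, marker, channel = "MAP"),
    pre_post_summary(session$channels$TSI, marker, channel = "TSI"),
    pre_post_summary(session$channels$PO2, marker, channel = "PO2")
  )
  summaries$animal <- id

  detections <- dplyr::bind_rows(lapply(c("MAP", "TSI", "PO2"), function(ch) {
    first_change_time(session$channels[[ch]], marker, direction = "falling",
                      k = k, persistence = persistence, channel = ch)
  }))
  detections$animal <- id

  zwin <- c(marker - 600, marker - 300)
  abp_z <- zscore_ts(session$channels$ABP, zwin)
  o2hb_z <- zscore_ts(session$channels$O2Hb, zwin)
  pulse <- three_window_analysis(abp_z, o2hb_z, marker, spec = spec)
  pulse$animal <- id

  structure(
    list(animal = id, offset_nirs = offset, summaries = summaries,
         detections = detections, pulse = pulse, session = session),
    class = "arrest_analysis"
  )
}

#' Cohort-level analysis
#'
#' Applies [analyze_animal()] to every animal of a simulated (or loaded)
#' cohort and assembles the cohort outputs: the per-channel
#' baseline/euthanasia table with Mean and SD rows, the detection-latency
#' table with paired channel comparisons, the pooled pulse table, and the
#' paired t-tests of the baseline-vs-euthanasia contrast per channel.
#' Channels flagged as absent in a config (attributes `map_present` /
#' `po2_present`) are excluded channel-wise, mirroring recordings lost to
#' signal quality or protocol changes.
#'
#' @param cohort An `arrest_cohort` from [simulate_cohort()].
#' @param ... Passed to [analyze_animal()].
#' @return A list of class `cohort_analysis`: `per_animal` (list),
#'   `summaries`, `table` (from [cohort_table()]), `latency` (from
#'   [latency_table()]), `pulse`, `tests`.
#' @export
analyze_cohort <- function(cohort, ...) {
  per <- lapply(cohort$animals, analyze_animal, ...)
  drop_missing <- function(df, cfg) {
    keep <- rep(TRUE, nrow(df))
    if (isFALSE(attr(cfg, "map_present"))) keep <- keep & df$channel != "MAP"
    if (isFALSE(attr(cfg, "po2_present"))) keep <- keep & df$channel != "PO2"
    df[keep, ]
  }
  summaries <- dplyr::bind_rows(purrr::map2(
    per, cohort$configs, function(a, cfg) drop_missing(a$summaries, cfg)))
  detections <- dplyr::bind_rows(purrr::map2(
    per, cohort$configs, function(a, cfg) drop_missing(a$detections, cfg)))
  pulse <- dplyr::bind_rows(purrr::map(per, "pulse"))

  tests <- summaries |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(d, g) {
      paired_t(d$baseline_mean, d$post_value)
    }) |>
    dplyr::ungroup()

  structure(
    list(per_animal = per, summaries = summaries,
         table = cohort_table(summaries),
         latency = latency_table(detections),
         detections = detections, pulse = pulse, tests = tests),
    class = "cohort_analysis"
  )
}
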
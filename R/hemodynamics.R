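#' Mean arterial pressure from the pressure waveform
#'
#' Per beat-scale sliding window (default 1 s), systolic pressure is the
#' window maximum and diastolic the window minimum, and
#' `MAP = systolic / 3 + 2 diastolic / 3`. Sliding extrema are used instead
#' of beat segmentation because they stay well-defined when pulsation
#' vanishes after arrest: the extrema converge and MAP tends to the
#' instantaneous pressure, which is the physically correct limit. The
#' result is returned on the common 10-Hz grid.
#'
#' @param abp A [time_series()] of arterial pressure at >= 10 Hz.
#' @param window Sliding window length (s).
#' @param target_fs Output rate (Hz).
#' @return A [time_series()] of MAP (mmHg).
#' @export
map_trace <- function(abp, window = 1.0, target_fs = 10) {
  if (length(abp) == 0) stop("empty pressure trace", call. = FALSE)
  if (abp$fs < 10) stop("pressure trace must be sampled at >= 10 Hz", call. = FALSE)
  k <- max(3, round(window * abp$fs))
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  x <- c(rep(abp$values[1], half), abp$values,
         rep(abp$values[length(abp$values)], half))
  sys <- zoo::rollmax(x, k, align = "center")
  dia <- -zoo::rollmax(-x, k, align = "center")
  map <- sys / 3 + 2 * dia / 3
  if (!isTRUE(all.equal(abp$fs, target_fs))) {
    step <- abp$fs / target_fs
    if (isTRUE(all.equal(step, round(step)))) {
      map <- map[seq(1, length(map), by = round(step))]
    } else {
      map <- resample_ts(
        time_series(map, abp$fs, abp$t0, "mmHg", "MAP"), target_fs)$values
    }
  }
  # MAP is by definition a per-cycle mean: smooth the extrema estimate over
  # the same beat-scale window (centred, zero-phase), which also removes the
  # plateau distortion the sliding extrema impose on slow oscillations
  k2 <- max(3, round(window * target_fs))
  if (k2 %% 2 == 0) k2 <- k2 + 1
  h2 <- (k2 - 1) / 2
  map <- zoo::rollmean(c(rep(map[1], h2), map, rep(map[length(map)], h2)), k2)
  time_series(map, target_fs, abp$t0, units = "mmHg", label = "MAP")
}

#' Baseline vs euthanasia summary of one channel
#'
#' Baseline is the mean over the 60 s preceding the marker; the euthanasia
#' value is the mean over the final `post_dur` seconds of the `post_at`-s
#' post-marker window (default: last 10 s of the 5-min capture); `delta` is
#' the signed difference (post minus baseline).
#'
#' @param ts A [time_series()].
#' @param marker Marker time (s).
#' @param channel Channel label for the output row (defaults to the trace
#'   label).
#' @param baseline_dur Baseline window length (s).
#' @param post_at End of the post window, relative to the marker (s).
#' @param post_dur Length of the terminal averaging window (s).
#' @return A one-row tibble: `channel`, `baseline_mean`, `post_value`,
#'   `delta`.
#' @export
pre_post_summary <- function(ts, marker, channel = ts$label,
                             baseline_dur = 60, post_at = 300,
                             post_dur = 10) {
  b <- mean(ts_window(ts, marker - baseline_dur, marker,
                      require_full = TRUE)$values, na.rm = TRUE)
  p <- mean(ts_window(ts, marker + post_at - post_dur, marker + post_at,
                      require_full = TRUE)$values, na.rm = TRUE)
  tibble::tibble(channel = channel, baseline_mean = b, post_value = p,
                 delta = p - b)
}

#' Cohort summary table with Mean and SD rows
#'
#' Per-channel arithmetic mean and sample SD (n - 1 denominator) of the
#' baseline, euthanasia and delta columns across animals, excluding missing
#' animals channel-wise (so each channel keeps its own n).
#'
#' @param summaries A data frame with columns `animal`, `channel`,
#'   `baseline_mean`, `post_value`, `delta` (one row per animal x channel;
#'   `NA` rows count as missing).
#' @return A tibble with one row per channel: `channel`, `n`, then
#'   `mean`/`sd` of the three columns.
#' @export
cohort_table <- function(summaries) {
  summaries |>
    dplyr::filter(!is.na(.data$baseline_mean), !is.na(.data$post_value)) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n = dplyr::n(),
      baseline_sd = stats::sd(.data$baseline_mean),
      baseline_mean = mean(.data$baseline_mean),
      post_sd = stats::sd(.data$post_value),
      post_mean = mean(.data$post_value),
      delta_sd = stats::sd(.data$delta),
      delta_mean = mean(.data$delta),
      .groups = "drop"
    ) |>
    dplyr::select("channel", "n", "baseline_mean", "baseline_sd",
                  "post_mean", "post_sd", "delta_mean", "delta_sd")
}
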
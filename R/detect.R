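#' Time to first 2-SD excursion beyond baseline
#'
#' The arrest-onset statistic: the latency from the infusion marker to the
#' first post-marker sample (or first run of `persistence` consecutive
#' samples) strictly beyond `baseline_mean -/+ k * baseline_sd`, where the
#' baseline mean and SD are both taken over the minute preceding the
#' marker. Ties exactly at the threshold do not trigger. If no crossing
#' occurs within the post window, the latency is `NA` but the threshold
#' and baseline statistics are still reported.
#'
#' @param ts A [time_series()].
#' @param marker Marker time (s); must lie inside the recording with a full
#'   baseline window before it.
#' @param direction `"falling"` (excursion below threshold, default) or
#'   `"rising"`.
#' @param k SD multiplier (default 2).
#' @param persistence Number of consecutive beyond-threshold samples
#'   required (default 1: the strict first-drop reading; raise it to make
#'   the statistic robust to single-sample noise).
#' @param baseline_dur Baseline window length (s).
#' @param post_dur Length of the searched post-marker window (s).
#' @param channel Label for the result (defaults to the trace label).
#' @return A one-row tibble of class `detection_result`: `channel`,
#'   `latency`, `detected`, `threshold`, `baseline_mean`, `baseline_sd`,
#'   `k`, `direction`, `persistence`.
#' @export
first_change_time <- function(ts, marker, direction = c("falling", "rising"),
                              k = 2, persistence = 1, baseline_dur = 60,
                              post_dur = 300, channel = ts$label) {
  direction <- match.arg(direction)
  if (marker < ts$t0 || marker > ts_end(ts)) {
    stop("marker lies outside the recording", call. = FALSE)
  }
  base <- ts_window(ts, marker - baseline_dur, marker, require_full = TRUE)
  m <- mean(base$values)
  s <- stats::sd(base$values)
  if (!is.finite(s) || s <= .Machine$double.eps^0.5) {
    stop(sprintf("degenerate baseline: channel '%s' has zero SD", channel),
         call. = FALSE)
  }
  thr <- if (direction == "falling") m - k * s else m + k * s
  post <- ts_window(ts, marker, min(marker + post_dur, ts_end(ts)) + 1 / ts$fs)
  beyond <- if (direction == "falling") post$values < thr else post$values > thr
  latency <- NA_real_
  r <- rle(beyond)
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit)) {
    i <- if (hit[1] == 1) 1L else sum(r$lengths[seq_len(hit[1] - 1)]) + 1L
    latency <- (ts_time(post)[i]) - marker
  }
  out <- tibble::tibble(
    channel = channel, latency = latency, detected = !is.na(latency),
    threshold = thr, baseline_mean = m, baseline_sd = s, k = k,
    direction = direction, persistence = persistence
  )
  class(out) <- c("detection_result", class(out))
  out
}

#' Per-channel latency summary and paired comparisons
#'
#' Mean and sample SD of the detection latencies per channel, plus paired
#' t-tests between channels restricted to the animals in which both
#' channels produced a detection (so each comparison keeps its own n).
#'
#' @param results Data frame with columns `animal`, `channel`, `latency`.
#' @return A list with `summary` (channel, n, mean_s, sd_s) and
#'   `comparisons` (channel_a, channel_b, n, mean_diff_s, t, df, p).
#' @export
latency_table <- function(results) {
  ok <- dplyr::filter(results, !is.na(.data$latency))
  summ <- ok |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n = dplyr::n(), mean_s = mean(.data$latency),
                     sd_s = stats::sd(.data$latency), .groups = "drop")
  chans <- unique(ok$channel)
  comparisons <- NULL
  if (length(chans) >= 2) {
    pairs <- utils::combn(chans, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      wide <- ok |>
        dplyr::filter(.data$channel %in% pr) |>
        tidyr::pivot_wider(id_cols = "animal", names_from = "channel",
                           values_from = "latency") |>
        tidyr::drop_na()
      if (nrow(wide) < 2) {
        return(tibble::tibble(channel_a = pr[1], channel_b = pr[2],
                              n = nrow(wide), mean_diff_s = NA_real_,
                              t = NA_real_, df = NA_real_, p = NA_real_))
      }
      tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
      tibble::tibble(channel_a = pr[1], channel_b = pr[2], n = nrow(wide),
                     mean_diff_s = unname(tt$estimate),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    })
  }
  list(summary = summ, comparisons = comparisons)
}
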
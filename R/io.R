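#' Write one channel to CSV
#'
#' Two data columns (`time_s`, `value`) preceded by `#`-comment header
#' lines carrying the channel name, units, sampling rate and animal id, so
#' a file is self-describing without a side-car.
#'
#' @param ts A [time_series()].
#' @param path Output file.
#' @param animal_id Animal label for the header.
#' @return Invisibly, `path`.
#' @export
write_channel_csv <- function(ts, path, animal_id = "") {
  hdr <- c(
    sprintf("# channel: %s", ts$label),
    sprintf("# units: %s", ts$units),
    sprintf("# fs_hz: %g", ts$fs),
    sprintf("# animal_id: %s", animal_id)
  )
  writeLines(c(hdr, "time_s,value"), path)
  utils::write.table(
    data.frame(time_s = ts_time(ts), value = ts$values),
    path, sep = ",", row.names = FALSE, col.names = FALSE, append = TRUE
  )
  invisible(path)
}

#' Read a channel CSV written by [write_channel_csv()]
#'
#' @param path File path.
#' @return A [time_series()]; the rate is taken from the header and checked
#'   against the time column.
#' @export
read_channel_csv <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return("")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  fs <- as.numeric(get("fs_hz"))
  if (!is.finite(fs)) fs <- 1 / stats::median(diff(df$time_s))
  time_series(df$value, fs, t0 = df$time_s[1],
              units = get("units"), label = get("channel"))
}

#' Write one simulated experiment to a directory
#'
#' One CSV per channel (the optical recording becomes one
#' `A_<wavelength>_<distance>` column per channel), an events CSV with the
#' infusion marker, the ground-truth crossing table, and the configuration
#' as YAML.
#'
#' @param sim An `arrest_sim` from [simulate_animal()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$config$animal_id
  files <- c(
    write_channel_csv(sim$abp, file.path(dir, "abp.csv"), id),
    write_channel_csv(sim$po2, file.path(dir, "po2.csv"), id)
  )
  # optical recording: wide CSV, one attenuation column per channel
  att <- sim$optics$attenuation
  n <- dim(att)[1]
  df <- data.frame(time_s = sim$optics$t0 + (seq_len(n) - 1) / sim$optics$fs)
  for (w in seq_along(sim$optics$wavelengths)) {
    for (j in seq_along(sim$optics$distances)) {
      df[[sprintf("A_%g_%g", sim$optics$wavelengths[w],
                  sim$optics$distances[j])]] <- att[, w, j]
    }
  }
  f <- file.path(dir, "optics.csv")
  utils::write.csv(df, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "events.csv")
  utils::write.csv(
    data.frame(marker = "pentobarbital_infusion", time_s = sim$marker),
    f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.csv")
  utils::write.csv(sim$truth$crossings, f, row.names = FALSE)
  files <- c(files, f)
  cfg <- sim$config
  cfg$artifact_schedule <- as.data.frame(cfg$artifact_schedule)
  f <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), f)
  files <- c(files, f)
  invisible(files)
}

#' Read an optical recording written by [write_session()]
#'
#' @param path Path to the wide-format optics CSV.
#' @param fs Sampling rate (Hz) of the file.
#' @return An [optical_recording()].
#' @export
read_optics_csv <- function(path, fs = 10) {
  df <- utils::read.csv(path)
  cols <- grep("^A_", names(df), value = TRUE)
  parts <- do.call(rbind, strsplit(sub("^A_", "", cols), "_"))
  wl <- sort(unique(as.numeric(parts[, 1])))
  dist <- sort(unique(as.numeric(parts[, 2])))
  att <- array(NA_real_, dim = c(nrow(df), length(wl), length(dist)))
  for (ci in seq_along(cols)) {
    w <- match(as.numeric(parts[ci, 1]), wl)
    j <- match(as.numeric(parts[ci, 2]), dist)
    att[, w, j] <- df[[cols[ci]]]
  }
  optical_recording(att, fs, t0 = df$time_s[1], wavelengths = wl,
                    distances = dist)
}
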
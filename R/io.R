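#' Read one channel from a Neuroscope-style flat binary file
#'
#' Neuroscope `.lfp`/`.dat` files are 16-bit signed little-endian integers,
#' channel-multiplexed (sample-major: ch0 s0, ch1 s0, ..., ch0 s1, ...).
#' Channel indexing is 0-based, matching Neuroscope's display.
#'
#' @param path File path.
#' @param n_channels Number of interleaved channels (> 0).
#' @param channel 0-based channel index to extract.
#' @param rate Sampling rate in Hz.
#' @param gain Multiplier applied to the raw integer values (default 1).
#' @return A [signal_trace()].
#' @export
read_lfp_channel <- function(path, n_channels, channel, rate, gain = 1) {
  if (!file.exists(path)) stop_format(sprintf("File not found: %s", path))
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1) stop_invalid("`n_channels` must be >= 1.")
  if (channel < 0 || channel >= n_channels) {
    stop_invalid(sprintf("`channel` must be in [0, %d].", n_channels - 1L))
  }
  sz <- file.info(path)$size
  if (sz %% (2L * n_channels) != 0) {
    stop_format(sprintf(
      "Corrupt file: %d bytes is not a multiple of 2 x %d channels.",
      sz, n_channels
    ))
  }
  n_samples <- sz / (2L * n_channels)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_samples * n_channels, size = 2L,
                 signed = TRUE, endian = "little")
  signal_trace(raw[seq(channel + 1L, length(raw), by = n_channels)] * gain, rate)
}

#' Write channels to a Neuroscope-style flat binary file
#'
#' @param traces A list of [signal_trace()]s (or numeric vectors) of equal
#'   length; values are rounded and clamped to the int16 range.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfp_bin <- function(traces, path) {
  vecs <- lapply(traces, function(x) if (inherits(x, "signal_trace")) x$samples else as.numeric(x))
  n <- unique(vapply(vecs, length, integer(1)))
  if (length(n) != 1) stop_invalid("All channels must have the same length.")
  mat <- do.call(rbind, vecs)                       # channels x samples
  flat <- as.integer(pmin(pmax(round(mat), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a motion (speed) trace from CSV/TSV
#'
#' Accepts two dialects: two columns `(time_s, speed)` with monotonically
#' increasing time (non-uniform timestamps are resampled onto a uniform grid
#' with a warning), or a single `speed` column with the rate given either as a
#' `# rate: <Hz>` comment line or via the `rate` argument.
#'
#' @param path File path (comma- or tab-separated; header required).
#' @param rate Sampling rate override for one-column files (default 300 Hz).
#' @return A [signal_trace()].
#' @export
read_motion_csv <- function(path, rate = 300) {
  if (!file.exists(path)) stop_format(sprintf("File not found: %s", path))
  first <- readLines(path, n = 5)
  cmt <- grep("^#", first, value = TRUE)
  rate_line <- grep("rate", cmt, value = TRUE)
  if (length(rate_line) > 0) {
    rate <- as.numeric(sub(".*rate[^0-9.]*([0-9.]+).*", "\\1", rate_line[1]))
  }
  sep <- if (grepl("\t", first[length(cmt) + 1])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  if (ncol(df) >= 2) {
    time <- df[[1]]; speed <- df[[2]]
    if (any(diff(time) <= 0)) stop_format("Time column must be strictly increasing.")
    dt <- diff(time)
    est_rate <- 1 / median(dt)
    if (max(abs(dt - median(dt))) > 1e-6 * median(dt)) {
      warn("Non-uniform timestamps; resampling onto a uniform grid.")
      grid <- seq(time[1], time[length(time)], by = 1 / est_rate)
      speed <- approx(time, speed, xout = grid, rule = 2)$y
      time <- grid
    }
    signal_trace(speed, est_rate, start_time = time[1])
  } else {
    signal_trace(df[[1]], rate)
  }
}

#' Write a motion trace as a two-column CSV
#'
#' @param x A [signal_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(x, path) {
  utils::write.csv(
    data.frame(time_s = trace_times(x), speed = x$samples),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a scored session to disk
#'
#' Writes `states.tsv` (columns `start_s`, `end_s`, `label`), and
#' `diagnostics.txt` (plain key/value lines: thresholds, effectiveness,
#' parameter echo).
#'
#' @param scoring A `state_scoring` from [score_session()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_scoring <- function(scoring, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intervals_tsv(
    scoring$states |> select(start = "start", end = "end", label = "state"),
    file.path(dir, "states.tsv")
  )
  d <- scoring$diagnostics
  kv <- c(
    sprintf("mode\t%s", d$mode),
    sprintf("speed_threshold\t%.6g", d$speed_threshold),
    sprintf("sws_threshold\t%.6g",
            if (is.null(d$sws_threshold)) NA else d$sws_threshold$threshold),
    sprintf("sws_effectiveness\t%.6g",
            if (is.null(d$sws_threshold)) NA else d$sws_threshold$effectiveness),
    sprintf("rem_threshold\t%.6g", d$rem_threshold),
    sprintf("session_duration_s\t%.4f", d$session_duration),
    sprintf("immobility_s\t%.4f", interval_duration(scoring$immobility)),
    vapply(c("sws", "rem", "quiet_wake", "freezing"), function(s) {
      sprintf("%s_s\t%.4f", s, interval_duration(scoring[[s]]))
    }, character(1)),
    param_echo(scoring$params)
  )
  writeLines(kv, file.path(dir, "diagnostics.txt"))
  invisible(dir)
}

param_echo <- function(p) {
  num <- p[vapply(p, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  c(
    vapply(names(num), function(nm) sprintf("param.%s\t%.6g", nm, num[[nm]]),
           character(1)),
    vapply(c("spindle_band", "theta_band", "delta_band"), function(nm) {
      sprintf("param.%s\t%g-%g", nm, p[[nm]]$low, p[[nm]]$high)
    }, character(1))
  )
}
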
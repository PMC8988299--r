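#' Uniformly sampled signal trace
#'
#' Light container for a uniformly sampled real-valued series (an LFP channel,
#' an angular-speed trace, or any derived per-sample quantity) together with
#' its sampling rate and start time. All per-sample transforms in the package
#' take and return `signal_trace` objects; use [tibble::as_tibble()] to get a
#' `(time, value)` data frame for plotting or joining.
#'
#' @param samples Numeric vector, all values finite, length >= 1.
#' @param rate Sampling rate in samples per second (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `signal_trace`: a list with elements `samples`,
#'   `rate`, and `start_time`.
#' @examples
#' x <- signal_trace(sin(2 * pi * 7.5 * seq(0, 1, by = 1 / 250)), rate = 250)
#' x
#' head(tibble::as_tibble(x))
#' @export
signal_trace <- function(samples, rate, start_time = 0) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_invalid("`rate` must be a single positive number (samples/second).")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop_invalid("`samples` must contain at least one value.")
  if (!all(is.finite(samples))) stop_invalid("`samples` must be finite.")
  if (!is.numeric(start_time) || length(start_time) != 1 || !is.finite(start_time)) {
    stop_invalid("`start_time` must be a single finite number (seconds).")
  }
  structure(
    list(samples = samples, rate = rate, start_time = start_time),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "<signal_trace> %d samples @ %g Hz (%.2f s, start %.2f s)\n",
    length(x$samples), x$rate, trace_duration(x), x$start_time
  ))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' @rdname signal_trace
#' @param x A `signal_trace`.
#' @param ... Unused.
#' @export
as_tibble.signal_trace <- function(x, ...) {
  tibble(time = trace_times(x), value = x$samples)
}

#' Sample times and total duration of a trace
#'
#' `trace_times()` returns the time stamp of each sample; `trace_duration()`
#' the covered duration in seconds (n / rate).
#'
#' @param x A [signal_trace()].
#' @return Numeric vector of times, or a single duration in seconds.
#' @export
trace_times <- function(x) {
  x$start_time + (seq_along(x$samples) - 1) / x$rate
}

#' @rdname trace_times
#' @export
trace_duration <- function(x) length(x$samples) / x$rate

#' Frequency band definition
#'
#' A named frequency band with low and high edges in Hz. The scoring defaults
#' follow the common rodent conventions: spindle 9-17 Hz, theta 6-9 Hz,
#' delta 0.5-4 Hz.
#'
#' @param name Band label.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A list of class `band_definition` with elements `name`, `low`, `high`.
#' @examples
#' band_definition("spindle", 9, 17)
#' @export
band_definition <- function(name, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 || length(high) != 1 ||
      !is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop_invalid("Band edges must satisfy 0 < low < high (Hz).")
  }
  structure(list(name = as.character(name), low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

# validate a band against a trace's Nyquist frequency
check_band <- function(band, rate) {
  if (!inherits(band, "band_definition")) {
    if (is.numeric(band) && length(band) == 2) {
      band <- band_definition("band", band[1], band[2])
    } else {
      stop_invalid("`band` must be a band_definition or a numeric c(low, high).")
    }
  }
  if (band$high >= rate / 2) {
    stop_invalid(sprintf(
      "Band edge %g Hz is at or above the Nyquist frequency (%g Hz).",
      band$high, rate / 2
    ))
  }
  band
}
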
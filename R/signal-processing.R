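# mirror-pad a numeric vector by npad samples each side; reflection indices
# fold repeatedly, so npad may exceed the signal length
mirror_pad <- function(v, npad) {
  n <- length(v)
  npad <- as.integer(ceiling(npad))
  if (npad <= 0) return(list(x = v, npad = 0L))
  if (n == 1) return(list(x = rep(v, 2L * npad + 1L), npad = npad))
  fold <- function(p) {           # 0-based position -> valid 0-based index
    q <- p %% (2L * (n - 1L))
    ifelse(q > (n - 1L), 2L * (n - 1L) - q, q)
  }
  left <- v[fold((-npad):(-1)) + 1L]
  right <- v[fold(n:(n + npad - 1L)) + 1L]
  list(x = c(left, v, right), npad = npad)
}

# "same"-size convolution with a symmetric odd-length kernel, via FFT
conv_same <- function(v, kernel) {
  nk <- length(kernel)
  half <- (nk - 1L) %/% 2L
  p <- mirror_pad(v, half)
  n <- length(p$x)
  m <- nextn(n + nk - 1L, c(2L, 3L, 5L))
  fx <- fft(c(p$x, numeric(m - n)))
  fk <- fft(c(kernel, numeric(m - nk)))
  full <- Re(fft(fx * fk, inverse = TRUE)) / m
  out <- full[(half + 1):(half + n)]
  out[(p$npad + 1):(p$npad + length(v))]
}

#' Zero-phase band-pass filter
#'
#' Filters a trace with a 4th-order Butterworth band-pass applied forward and
#' backward ([signal::filtfilt()]), giving zero phase distortion so that
#' envelope timing stays aligned with behavior. The trace is mirror-padded
#' (three cycles of the band's low edge) before filtering to suppress edge
#' transients.
#'
#' @param x A [signal_trace()].
#' @param band A [band_definition()] or numeric `c(low, high)` in Hz; must lie
#'   below the Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @return A `signal_trace` of the same length and rate.
#' @details When the band's low edge is a tiny fraction of the Nyquist
#'   frequency (e.g. the 0.5 Hz delta edge on a 1250 Hz trace) the direct IIR
#'   design is numerically ill-conditioned; the trace is then filtered at an
#'   internally decimated rate and interpolated back, which is exact for the
#'   band-limited result.
#' @examples
#' x <- signal_trace(sin(2 * pi * 12 * seq(0, 10, by = 1 / 250)), 250)
#' y <- bandpass(x, band_definition("spindle", 9, 17))
#' @export
bandpass <- function(x, band, order = 4) {
  band <- check_band(band, x$rate)
  if (band$low / (x$rate / 2) < 0.02) {
    work_rate <- x$rate / max(2L, floor(x$rate / max(8 * band$high, 50)))
    low <- decimate_lfp(x, work_rate)
    flt <- bandpass(low, band, order = order)
    y <- stats::spline(trace_times(flt), flt$samples, xout = trace_times(x),
                       method = "fmm")$y
    return(signal_trace(y, x$rate, x$start_time))
  }
  bf <- signal::butter(order, c(band$low, band$high) / (x$rate / 2), type = "pass")
  p <- mirror_pad(x$samples, ceiling(3 * x$rate / band$low))
  y <- signal::filtfilt(bf, p$x)
  y <- y[(p$npad + 1):(p$npad + length(x$samples))]
  if (!all(is.finite(y))) {
    stop_invalid("Band-pass filter is numerically unstable for this band/rate.")
  }
  signal_trace(y, x$rate, x$start_time)
}

#' Instantaneous amplitude via the Hilbert transform
#'
#' Computes the analytic signal through the FFT (positive frequencies doubled,
#' negative zeroed) and returns its modulus: the instantaneous amplitude of a
#' band-limited trace. For a pure sinusoid `A * sin(2 pi f t)` the envelope
#' equals `A` away from the edges. The trace is mirror-extended to an
#' FFT-friendly length before transforming.
#'
#' @param x A [signal_trace()] (length >= 16).
#' @return A non-negative `signal_trace` of the same length and rate.
#' @export
hilbert_envelope <- function(x) {
  v <- x$samples
  n <- length(v)
  if (n < 16) stop_invalid("Envelope estimation requires at least 16 samples.")
  m <- nextn(n, c(2L, 3L, 5L))
  if (m > n) {
    ext <- min(m - n, n - 1L)
    v <- c(v, v[n:(n - ext + 1L)], numeric(m - n - ext))
  }
  X <- fft(v)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / m
  signal_trace(Mod(analytic[seq_len(n)]), x$rate, x$start_time)
}

#' Gaussian smoothing with a unit-sum kernel
#'
#' Smooths a trace by convolution with a symmetric, unit-sum Gaussian kernel,
#' so constant traces are fixed points and there is no group delay. `window`
#' is the total kernel support in seconds; the Gaussian SD is `window / 6`
#' (+/- 3 SD support). Pass `sd` to override that reading (e.g. `sd = window`).
#' The 14 s window is the scoring default for the spindle envelope; 8 s for
#' the cortical theta/delta ratio.
#'
#' @param x A [signal_trace()].
#' @param window Total kernel width in seconds (> 0).
#' @param sd Kernel standard deviation in seconds; default `window / 6`.
#' @return A `signal_trace` of the same length and rate. If the window is
#'   shorter than two sample periods a warning is issued and `x` is returned
#'   unchanged.
#' @export
gaussian_smooth <- function(x, window, sd = window / 6) {
  if (!is.numeric(window) || length(window) != 1 || !is.finite(window) || window <= 0) {
    stop_invalid("`window` must be a single positive number (seconds).")
  }
  if (window < 2 / x$rate) {
    warn("Smoothing window is shorter than two sample periods; returning input unchanged.")
    return(x)
  }
  sd_samp <- sd * x$rate
  half <- max(1L, ceiling(3 * sd_samp))
  kernel <- dnorm(seq(-half, half), sd = sd_samp)
  kernel <- kernel / sum(kernel)
  signal_trace(conv_same(x$samples, kernel), x$rate, x$start_time)
}

#' Binned band-power ratio (e.g. theta/delta)
#'
#' Band-passes the trace in the numerator and denominator bands, estimates
#' instantaneous power as the squared Hilbert envelope, averages it in
#' consecutive time bins, and returns the per-bin power ratio as a trace
#' sampled at `1 / bin` Hz. The theta (6-9 Hz) over delta (0.5-4 Hz) ratio is
#' the classical REM/SWS discriminator this implements.
#'
#' @param x A [signal_trace()].
#' @param num,den Numerator and denominator [band_definition()]s.
#' @param bin Bin width in seconds (default 1).
#' @return A `signal_trace` at rate `1 / bin`; bins with zero denominator
#'   power are reported as `Inf` with a warning.
#' @export
band_power_ratio <- function(x, num, den, bin = 1) {
  if (!is.numeric(bin) || length(bin) != 1 || !is.finite(bin) || bin <= 0) {
    stop_invalid("`bin` must be a single positive number (seconds).")
  }
  pow_num <- hilbert_envelope(bandpass(x, num))$samples^2
  pow_den <- hilbert_envelope(bandpass(x, den))$samples^2
  per_bin <- max(1L, round(bin * x$rate))
  n_bins <- length(pow_num) %/% per_bin
  if (n_bins < 1) stop_invalid("Trace shorter than one bin.")
  idx <- rep(seq_len(n_bins), each = per_bin)
  used <- seq_len(n_bins * per_bin)
  mn <- as.numeric(rowsum(pow_num[used], idx)) / per_bin
  md <- as.numeric(rowsum(pow_den[used], idx)) / per_bin
  ratio <- ifelse(md > 0, mn / md, Inf)
  if (any(!is.finite(ratio))) {
    warn("Zero denominator power in some bins; ratio reported as Inf there.")
  }
  structure(
    list(samples = ratio, rate = 1 / bin, start_time = x$start_time),
    class = "signal_trace"
  )
}

#' Decimate a trace to a lower sampling rate
#'
#' Anti-alias low-pass filters (zero-phase Butterworth, cutoff 0.45 x target
#' rate) and takes every `rate / target_rate`-th sample. Content below
#' 0.4 x target rate is preserved; content above the new Nyquist frequency is
#' strongly attenuated. Non-integer factors are resampled through
#' [signal::resample()] after the same anti-alias filter.
#'
#' @param x A [signal_trace()].
#' @param target_rate Desired rate in samples/second (<= `x$rate`).
#' @return A `signal_trace` at `target_rate`.
#' @export
decimate_lfp <- function(x, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      !is.finite(target_rate) || target_rate <= 0) {
    stop_invalid("`target_rate` must be a single positive number.")
  }
  if (target_rate > x$rate) {
    stop_invalid("`target_rate` exceeds the trace's sampling rate.")
  }
  if (target_rate == x$rate) return(x)
  bf <- signal::butter(8, 0.9 * target_rate / x$rate, type = "low")
  p <- mirror_pad(x$samples, ceiling(3 * x$rate / target_rate))
  y <- signal::filtfilt(bf, p$x)
  y <- y[(p$npad + 1):(p$npad + length(x$samples))]
  q <- x$rate / target_rate
  if (abs(q - round(q)) < 1e-9) {
    out <- y[seq(1, length(y), by = round(q))]
  } else {
    # non-integer factor: the anti-aliased signal is band-limited well below
    # the original Nyquist, so interpolation onto the new grid is accurate
    n_out <- floor(length(y) * target_rate / x$rate)
    t_out <- x$start_time + (0:(n_out - 1)) / target_rate
    out <- approx(trace_times(x), y, xout = t_out, rule = 2)$y
  }
  signal_trace(out, target_rate, x$start_time)
}

#' Morlet wavelet spectrogram
#'
#' Time-frequency power via the continuous Morlet wavelet transform (center
#' frequency parameter `omega0`, default 6), computed in the frequency domain.
#' Used for visualization only; no detector consumes it.
#'
#' @param x A [signal_trace()].
#' @param freqs Frequencies of interest in Hz, all within `(0, rate / 2)`.
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return A matrix of non-negative power, one row per frequency (rownames =
#'   frequency), one column per sample, with attributes `freqs`, `rate`,
#'   `times`.
#' @export
wavelet_spectrogram <- function(x, freqs, omega0 = 6) {
  if (any(freqs <= 0) || any(freqs >= x$rate / 2)) {
    stop_invalid("`freqs` must lie strictly within (0, rate/2).")
  }
  v <- x$samples
  n <- length(v)
  m <- nextn(2L * n, c(2L, 3L, 5L))
  X <- fft(c(v, numeric(m - n)))
  w <- 2 * pi * (0:(m - 1)) / m * x$rate
  w[w > pi * x$rate] <- w[w > pi * x$rate] - 2 * pi * x$rate  # signed frequencies
  pow <- matrix(0, nrow = length(freqs), ncol = n)
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  for (i in seq_along(freqs)) {
    scale <- fourier_factor / freqs[i]
    psi <- pi^(-0.25) * exp(-((scale * w - omega0)^2) / 2) * (w > 0)
    psi <- psi * sqrt(2 * pi * scale * x$rate)  # unit-energy normalization
    wt <- fft(X * psi, inverse = TRUE) / m
    pow[i, ] <- Mod(wt[seq_len(n)])^2
  }
  rownames(pow) <- as.character(freqs)
  attr(pow, "freqs") <- freqs
  attr(pow, "rate") <- x$rate
  attr(pow, "times") <- trace_times(x)
  pow
}
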
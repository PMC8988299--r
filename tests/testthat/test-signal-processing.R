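sine_trace <- function(freq, rate = 1250, dur = 30, amp = 1) {
  signal_trace(amp * sin(2 * pi * freq * (0:(dur * rate - 1)) / rate), rate)
}

spindle <- band_definition("spindle", 9, 17)

test_that("band-pass passes in-band tones and rejects out-of-band tones", {
  x <- sine_trace(12)
  y <- bandpass(x, spindle)
  i <- (2 * 1250):(28 * 1250)    # trim 2 s edges
  expect_gt(cor(y$samples[i], x$samples[i]), 0.99)
  expect_equal(mean(abs(y$samples[i] / x$samples[i] - 1)[abs(x$samples[i]) > 0.5]),
               0, tolerance = 0.05)

  # 4 Hz tone: compare against the ideal FFT band-mask oracle
  x4 <- sine_trace(4)
  y4 <- bandpass(x4, spindle)
  oracle <- fft_band_mask(x4$samples, 9, 17, 1250)
  rms <- function(v) sqrt(mean(v^2))
  expect_lte(rms(y4$samples[i]), 0.1 * rms(x4$samples[i]))
  expect_lte(abs(rms(y4$samples[i]) - rms(oracle[i])), 0.05 * rms(x4$samples[i]))

  z <- bandpass(signal_trace(numeric(1000) + 0, 1250), spindle)
  expect_equal(max(abs(z$samples)), 0)
  expect_error(bandpass(sine_trace(5, rate = 30), band_definition("b", 9, 17)),
               class = "spindlescore_invalid_parameter")
})

test_that("band-pass is linear and length/rate preserving", {
  set.seed(1)
  x <- signal_trace(rnorm(5000), 250)
  y <- signal_trace(rnorm(5000), 250)
  a <- 2.5; b <- -1.25
  lhs <- bandpass(signal_trace(a * x$samples + b * y$samples, 250), spindle)
  rhs <- a * bandpass(x, spindle)$samples + b * bandpass(y, spindle)$samples
  expect_equal(lhs$samples, rhs, tolerance = 1e-8)
  expect_equal(length(lhs$samples), 5000)
  expect_equal(lhs$rate, 250)
})

test_that("Hilbert envelope recovers amplitude and modulation", {
  x <- sine_trace(12, amp = 2)
  env <- hilbert_envelope(x)
  i <- (1250):(29 * 1250)
  expect_true(all(env$samples >= 0))
  expect_lt(max(abs(env$samples[i] - 2)), 0.02)

  z <- hilbert_envelope(signal_trace(numeric(100), 1250))
  expect_equal(max(z$samples), 0, tolerance = 1e-12)

  # AM tone: envelope should match the known analytic modulation
  rate <- 1250; t <- (0:(30 * rate - 1)) / rate
  mod <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  am <- signal_trace(mod * sin(2 * pi * 12 * t), rate)
  env_am <- hilbert_envelope(am)
  ii <- (2 * rate):(28 * rate)
  rms_err <- sqrt(mean((env_am$samples[ii] - mod[ii])^2)) / sqrt(mean(mod[ii]^2))
  expect_lt(rms_err, 0.05)

  # envelope dominates the band-passed magnitude for narrowband input
  bp <- bandpass(x, spindle)
  expect_true(all(hilbert_envelope(bp)$samples[i] >= abs(bp$samples[i]) - 1e-6))
})

test_that("Gaussian smoothing has a unit-sum symmetric kernel", {
  const <- signal_trace(rep(3.7, 1000), 100)
  expect_equal(gaussian_smooth(const, 2)$samples, const$samples, tolerance = 1e-9)

  imp <- signal_trace(c(numeric(500), 1, numeric(500)), 100)
  k <- gaussian_smooth(imp, 1)$samples
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_equal(which.max(k), 501)            # zero group delay
  expect_equal(k[501 - 20], k[501 + 20], tolerance = 1e-12)

  set.seed(2)
  x <- signal_trace(rnorm(20000) + 10, 100)  # interior-dominated, nonzero mean
  expect_equal(mean(gaussian_smooth(x, 5)$samples), mean(x$samples), tolerance = 1e-4)

  expect_warning(gaussian_smooth(signal_trace(rnorm(100), 10), 0.05),
                 "shorter than two sample periods")
})

test_that("smoothing joins bursts: troughs rise above half plateau for close bursts", {
  # analytic oracle: convolve the same square burst train with the same kernel
  rate <- 50; dur <- 120
  t <- (0:(dur * rate - 1)) / rate
  burst_train <- function(gap) {
    on <- ((t %% (1 + gap)) < 1) & t > 20 & t < 100   # 1 s bursts, `gap` s apart
    as.numeric(on)
  }
  x <- burst_train(5)   # bursts < 7 s apart
  sm <- gaussian_smooth(signal_trace(x, rate), 14)$samples
  sd_samp <- 14 / 6 * rate
  kk <- dnorm(seq(-3 * sd_samp, 3 * sd_samp), sd = sd_samp)
  oracle <- stats::filter(c(rep(0, 2000), x, rep(0, 2000)), kk / sum(kk), sides = 2)
  oracle <- as.numeric(oracle)[2001:(2000 + length(x))]
  mid <- t > 40 & t < 80
  plateau <- max(sm[mid])
  expect_gt(min(sm[mid]), plateau / 2)
  expect_equal(sm[mid], oracle[mid], tolerance = 1e-6)
})

test_that("band-power ratio separates theta- from delta-dominated signals", {
  theta <- band_definition("theta", 6, 9)
  delta <- band_definition("delta", 0.5, 4)
  r_theta <- band_power_ratio(sine_trace(7.5), theta, delta)
  expect_true(all(r_theta$samples > 10))
  expect_equal(r_theta$rate, 1)
  r_delta <- band_power_ratio(sine_trace(2), theta, delta)
  expect_true(all(r_delta$samples < 0.1))

  # equal-amplitude mixture: expected value from the FFT band-mask oracle
  rate <- 1250; t <- (0:(30 * rate - 1)) / rate
  mix <- sin(2 * pi * 7.5 * t) + sin(2 * pi * 2 * t)
  r_mix <- band_power_ratio(signal_trace(mix, rate), theta, delta)
  p_th <- mean(fft_band_mask(mix, 6, 9, rate)^2)
  p_de <- mean(fft_band_mask(mix, 0.5, 4, rate)^2)
  inner <- r_mix$samples[5:25]
  expect_true(all(inner > 0.5 & inner < 2))
  expect_equal(median(inner), p_th / p_de, tolerance = 0.2)
})

test_that("decimation preserves the passband and suppresses aliases", {
  rate <- 20000
  t20 <- (0:(10 * rate - 1)) / rate
  x <- signal_trace(sin(2 * pi * 12 * t20), rate)
  d <- decimate_lfp(x, 1250)
  expect_equal(d$rate, 1250)
  direct <- sin(2 * pi * 12 * (0:(length(d$samples) - 1)) / 1250)
  i <- 2500:(length(direct) - 2500)
  expect_lt(max(abs(d$samples[i] - direct[i])), 0.01)

  expect_identical(decimate_lfp(x, rate), x)
  expect_error(decimate_lfp(d, 20000), class = "spindlescore_invalid_parameter")

  # content below 0.4 x target is preserved (100 Hz at target 300)
  t1250 <- (0:(10 * 1250 - 1)) / 1250
  x100 <- signal_trace(sin(2 * pi * 100 * t1250), 1250)
  d100 <- decimate_lfp(x100, 300)   # non-integer factor
  rms <- function(v) sqrt(mean(v^2))
  j <- 300:(length(d100$samples) - 300)
  expect_gt(rms(d100$samples[j]), 0.9 * rms(x100$samples))

  # content above the new Nyquist (160 Hz > 150 Hz) is attenuated >= 20 dB
  x160 <- signal_trace(sin(2 * pi * 160 * t1250), 1250)
  d160 <- decimate_lfp(x160, 300)
  expect_lt(rms(d160$samples[j]), 0.1 * rms(x160$samples))
})

test_that("wavelet spectrogram localizes tones in time and frequency", {
  rate <- 250
  x <- signal_trace(sin(2 * pi * 12 * (0:(20 * rate - 1)) / rate), rate)
  pow <- wavelet_spectrogram(x, freqs = 1:30)
  expect_true(all(pow >= 0))
  expect_equal(dim(pow), c(30, length(x$samples)))
  mid <- pow[, 5 * rate]
  expect_equal(unname(which.max(mid)), 12)

  # sequential tones: dominant row switches at the transition within 1 s
  t <- (0:(20 * rate - 1)) / rate
  y <- ifelse(t < 10, sin(2 * pi * 4 * t), sin(2 * pi * 12 * t))
  pow2 <- wavelet_spectrogram(signal_trace(y, rate), freqs = c(4, 12))
  dominant <- apply(pow2, 2, which.max)
  switch_at <- t[min(which(dominant == 2))]
  expect_lt(abs(switch_at - 10), 1)

  z <- wavelet_spectrogram(signal_trace(numeric(500), rate), freqs = c(4, 12))
  expect_equal(max(z), 0, tolerance = 1e-20)
})
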
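# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# ideal FFT band mask: zero all Fourier coefficients outside [low, high] Hz
fft_band_mask <- function(x, low, high, rate) {
  n <- length(x)
  f <- (0:(n - 1)) / n * rate
  f <- pmin(f, rate - f)  # folded (two-sided) frequency axis
  keep <- f >= low & f <= high
  Re(fft(fft(x) * keep, inverse = TRUE) / n)
}

# exhaustive 1-D two-group split minimizing within-group SSE;
# returns the size of the low group (over sorted values)
best_split_sse <- function(values) {
  v <- sort(values)
  n <- length(v)
  best_k <- 1L
  best <- Inf
  for (k in 1:(n - 1)) {
    g1 <- v[1:k]; g2 <- v[(k + 1):n]
    sse <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (sse < best - 1e-12) { best <- sse; best_k <- k }
  }
  list(k = best_k, sse = best, boundary = (mean(v[1:best_k]) + mean(v[(best_k + 1):n])) / 2)
}

# brute-force Otsu: between-class variance at every bin edge, computed
# directly from histogram counts and bin midpoints; returns the maximal
# variance and the set of edges attaining it (a gap between classes ties
# every edge crossing it)
brute_otsu <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  sb <- rep(-Inf, n_bins - 1)
  for (k in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    w0 <- n0 / (n0 + n1)
    sb[k] <- w0 * (1 - w0) * (mu0 - mu1)^2
  }
  best <- max(sb)
  list(best = best, edges = edges[which(sb >= best * (1 - 1e-9)) + 1])
}

expect_otsu_matches_brute <- function(values, n_bins = 256) {
  tr <- otsu_threshold(values, n_bins = n_bins)
  oracle <- brute_otsu(values, n_bins)
  expect_true(any(abs(oracle$edges - tr$threshold) < 1e-9 * max(1, abs(tr$threshold))))
}

# random valid interval set on [0, span]
random_intervals <- function(n, span = 100) {
  s <- sort(runif(2 * n, 0, span))
  spindlescore::intervals(s[seq(1, 2 * n, by = 2)], s[seq(2, 2 * n, by = 2)])
}
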
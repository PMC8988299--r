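new_threshold_result <- function(threshold, group_means, effectiveness, sizes,
                                 method) {
  structure(
    list(threshold = threshold, group_means = group_means,
         effectiveness = effectiveness, sizes = sizes, method = method),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result/%s> threshold %.4g | group means %.4g / %.4g (n = %d / %d) | m = %.3f\n",
    x$method, x$threshold, x$group_means[1], x$group_means[2],
    x$sizes[1], x$sizes[2], x$effectiveness
  ))
  invisible(x)
}

check_values <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop_invalid("Need at least 2 finite values.")
  rng <- range(values)
  if (diff(rng) <= 1e-12 * max(1, abs(rng[2]))) {
    stop_degenerate("All values are (numerically) identical; no two-group threshold exists.")
  }
  values
}

#' Two-cluster 1-D k-means threshold
#'
#' Computes the exact two-cluster k-means solution for a one-dimensional
#' sample: both clusters are contiguous runs of the sorted values, so the
#' global within-group sum-of-squares optimum is found by scanning all sorted
#' splits (prefix sums, deterministic, no initialization sensitivity). The
#' optimum is a fixed point of Lloyd's algorithm - every value is nearest its
#' own centroid - and the threshold is the midpoint of the two centroids,
#' which is the assignment boundary. This is the unsupervised threshold used
#' to separate high from low smoothed spindle power (and the theta/delta
#' groups of the standard scorer).
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return A `threshold_result` with `threshold`, ordered `group_means`,
#'   `effectiveness` (the separation metric `m` of the split, see
#'   [separation_effectiveness()]), and group `sizes`.
#' @examples
#' kmeans2_threshold(c(0, 0, 0, 10, 10, 10))
#' @export
kmeans2_threshold <- function(values) {
  values <- check_values(values)
  v <- sort(values)
  n <- length(v)
  csum <- cumsum(v); csum2 <- cumsum(v^2)
  # within-SSE of every split v[1..k] | v[(k+1)..n], via prefix sums
  k <- seq_len(n - 1L)
  s1 <- csum[k]; s2 <- csum[n] - s1
  q1 <- csum2[k]; q2 <- csum2[n] - q1
  sse <- (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
  k <- which.min(sse)   # first minimum: deterministic under ties
  g1 <- v[seq_len(k)]; g2 <- v[(k + 1):n]
  means <- c(mean(g1), mean(g2))
  assignment <- values > (means[1] + means[2]) / 2
  new_threshold_result(
    threshold = mean(means),
    group_means = means,
    effectiveness = separation_effectiveness(values, assignment),
    sizes = c(k, n - k),
    method = "kmeans2"
  )
}

#' Otsu histogram threshold
#'
#' Bins the values into `n_bins` equal-width bins and selects the bin edge
#' maximizing the between-class variance (equivalently minimizing the pooled
#' within-class variance) of the induced two-group split, using the bin
#' midpoints as class values. Deterministic for fixed input and `n_bins`.
#' Used as the REM threshold for the cortical theta/delta ratio, where the
#' fixed hippocampal threshold of 1 does not transfer.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @param n_bins Number of histogram bins (>= 2, default 256).
#' @return A `threshold_result`; group means/effectiveness are computed from
#'   the raw values split at the selected threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- check_values(values)
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2) {
    stop_invalid("`n_bins` must be at least 2.")
  }
  n_bins <- as.integer(n_bins)
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(
    pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance at thresholds after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  denom <- w0[k] * (1 - w0[k])
  sigma_b <- ifelse(denom > 0, (mu_t * w0[k] - mu[k])^2 / denom, -Inf)
  # a gap between the classes ties every edge crossing it: take the middle
  ties <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  kstar <- ties[ceiling(length(ties) / 2)]
  threshold <- edges[kstar + 1L]
  assignment <- values > threshold
  if (length(unique(assignment)) < 2) {
    stop_degenerate("Otsu split is one-sided; distribution is degenerate.")
  }
  new_threshold_result(
    threshold = threshold,
    group_means = c(mean(values[!assignment]), mean(values[assignment])),
    effectiveness = separation_effectiveness(values, assignment),
    sizes = c(sum(!assignment), sum(assignment)),
    method = "otsu"
  )
}

#' Separation effectiveness of a two-group split
#'
#' The proportion of variance explained by the grouping,
#' `m = 1 - sigma_i / sigma_tot`, where `sigma_i` is the group-size-weighted
#' mean of the within-group (population) variances and `sigma_tot` the
#' population variance of all values. By the law of total variance `m` lies in
#' `[0, 1]`: 1 when both groups are internally constant, 0 when the group
#' means coincide. Used to assess how well a smoothing window separates the
#' two spindle-power modes.
#'
#' @param values Numeric vector.
#' @param assignment Logical/binary vector (same length) giving the group of
#'   each value; both groups must be non-empty.
#' @return `m` in `[0, 1]`.
#' @examples
#' separation_effectiveness(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))  # 0.8
#' @export
separation_effectiveness <- function(values, assignment) {
  values <- as.numeric(values)
  if (length(assignment) != length(values)) {
    stop_invalid("`assignment` must have the same length as `values`.")
  }
  g <- as.logical(assignment)
  if (any(is.na(g))) stop_invalid("`assignment` must be binary without NA.")
  n <- length(values)
  n1 <- sum(!g); n2 <- sum(g)
  if (n1 == 0 || n2 == 0) stop_invalid("Both groups must be non-empty.")
  pvar <- function(x) mean((x - mean(x))^2)
  s_tot <- pvar(values)
  if (s_tot == 0) stop_degenerate("Total variance is zero.")
  s_i <- (n1 * pvar(values[!g]) + n2 * pvar(values[g])) / n
  m <- 1 - s_i / s_tot
  min(max(m, 0), 1)
}

#' Sweep the spindle-envelope smoothing window
#'
#' For each candidate window: smooth the raw spindle-band envelope, restrict
#' the samples to immobility (subsampled to one value per `subsample`
#' seconds), split them with [kmeans2_threshold()], and report the separation
#' effectiveness `m`. Longer windows join individual spindle events into a
#' sustained plateau, so `m` rises from short windows to a plateau around the
#' 14 s default.
#'
#' @param envelope_raw Unsmoothed spindle-band envelope ([signal_trace()]).
#' @param immobility Interval tibble of immobility.
#' @param windows Numeric vector of window widths in seconds.
#' @param subsample Spacing in seconds between retained samples (default 0.5).
#' @param window_is_sd If `TRUE` (default, matching [scoring_params()]) the
#'   windows are Gaussian SDs; otherwise total support (SD = window / 6).
#' @return A tibble with one row per window: `window`, `m`, `threshold`,
#'   `note` (`NA` or the error message for degenerate rows).
#' @export
smoothing_window_sweep <- function(envelope_raw, immobility, windows,
                                   subsample = 0.5, window_is_sd = TRUE) {
  if (length(windows) < 1) stop_invalid("Provide at least one window value.")
  purrr::map_dfr(windows, function(w) {
    res <- tryCatch({
      sm <- gaussian_smooth(envelope_raw, w, sd = if (window_is_sd) w else w / 6)
      vals <- restrict_samples(sm, immobility, subsample)
      tr <- kmeans2_threshold(vals)
      tibble(window = w, m = tr$effectiveness, threshold = tr$threshold,
             note = NA_character_)
    }, error = function(e) {
      tibble(window = w, m = NA_real_, threshold = NA_real_,
             note = conditionMessage(e))
    })
    res
  })
}

# samples of a trace whose times fall inside `iv`, thinned to one value per
# `subsample` seconds (decorrelates heavily smoothed series before clustering)
restrict_samples <- function(x, iv, subsample = NULL) {
  mask <- intervals_to_mask(iv, x$rate, length(x$samples), x$start_time)
  v <- x$samples
  if (!is.null(subsample) && subsample > 0) {
    step <- max(1L, round(subsample * x$rate))
    keep <- seq(1L, length(v), by = step)
    v <- v[keep]; mask <- mask[keep]
  }
  v[mask]
}
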
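#' Interval sets: ordered, disjoint, half-open epochs
#'
#' Behavioral epochs (immobility bouts, sleep periods, freezing bouts) are
#' represented as tibbles with numeric columns `start` and `end`, in seconds,
#' under the half-open convention `[start, end)`. `intervals()` builds such a
#' tibble from raw start/end vectors, sorting them and merging any overlapping
#' or touching pairs so the result is always ordered and pairwise disjoint.
#'
#' @param start,end Numeric vectors of equal length; each `start < end`, all
#'   values finite and non-negative.
#' @return A tibble with columns `start`, `end`, sorted by `start`, pairwise
#'   disjoint.
#' @examples
#' intervals(c(4, 0), c(6, 4.5))  # overlapping pair is merged
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) stop_invalid("`start` and `end` lengths differ.")
  if (length(start) == 0) return(tibble(start = numeric(), end = numeric()))
  if (!all(is.finite(start)) || !all(is.finite(end))) {
    stop_invalid("Interval times must be finite.")
  }
  if (any(start < 0)) stop_invalid("Interval times must be non-negative.")
  if (any(end <= start)) stop_invalid("Each interval must satisfy start < end.")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  # merge overlapping or touching neighbours (half-open: touching => merged)
  ms <- start[1]; me <- end[1]
  out_s <- numeric(length(start)); out_e <- numeric(length(start)); k <- 0L
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      k <- k + 1L; out_s[k] <- ms; out_e[k] <- me
      ms <- start[i]; me <- end[i]
    }
  }
  k <- k + 1L; out_s[k] <- ms; out_e[k] <- me
  tibble(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

empty_intervals <- function() tibble(start = numeric(), end = numeric())

#' Total covered duration of an interval set
#'
#' @param x An interval tibble (columns `start`, `end`).
#' @return Total duration in seconds.
#' @export
interval_duration <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

#' Convert a boolean sample mask to intervals
#'
#' Maximal runs of `TRUE` samples become half-open intervals
#' `[i / rate, (j + 1) / rate)` where `i`/`j` are the 0-based first/last run
#' indices, offset by `start_time`. Together with [intervals_to_mask()] this
#' round-trips exactly.
#'
#' @param mask Logical vector (non-empty; `NA` treated as `FALSE`).
#' @param rate Sampling rate of the mask in samples/second (> 0).
#' @param start_time Time of the first sample, seconds.
#' @return Interval tibble.
#' @examples
#' intervals_from_mask(c(FALSE, TRUE, TRUE, FALSE, TRUE), rate = 1)
#' @export
intervals_from_mask <- function(mask, rate, start_time = 0) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_invalid("`rate` must be a single positive number.")
  }
  mask <- as.logical(mask)
  if (length(mask) == 0) stop_invalid("`mask` must be non-empty.")
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty_intervals())
  intervals(
    start = start_time + (starts[keep] - 1L) / rate,
    end = start_time + ends[keep] / rate
  )
}

#' Rasterize intervals back to a boolean mask
#'
#' Inverse of [intervals_from_mask()]: sample `i` (0-based) is `TRUE` when its
#' time `start_time + i / rate` falls inside some interval.
#'
#' @param x Interval tibble.
#' @param rate Samples/second.
#' @param n Number of samples in the output mask.
#' @param start_time Time of the first sample, seconds.
#' @return Logical vector of length `n`.
#' @export
intervals_to_mask <- function(x, rate, n, start_time = 0) {
  mask <- logical(n)
  if (nrow(x) == 0) return(mask)
  for (i in seq_len(nrow(x))) {
    # first sample at time >= start, last sample at time < end
    lo <- ceiling((x$start[i] - start_time) * rate - 1e-9) + 1
    hi <- ceiling((x$end[i] - start_time) * rate - 1e-9)
    lo <- max(1, lo); hi <- min(n, hi)
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}

#' Merge intervals separated by brief gaps
#'
#' Consecutive intervals whose gap is strictly shorter than `max_gap` are
#' merged. This is the "ignore brief movements" mechanic used throughout the
#' scoring pipeline (0.2 s for freezing, 1 s for slow-wave sleep).
#'
#' @param x Interval tibble.
#' @param max_gap Maximum gap in seconds (>= 0); gaps `< max_gap` are closed.
#' @return Interval tibble with non-decreasing total duration.
#' @examples
#' close_gaps(intervals(c(0, 2.1), c(2, 4)), max_gap = 0.2)
#' @export
close_gaps <- function(x, max_gap) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || !is.finite(max_gap) || max_gap < 0) {
    stop_invalid("`max_gap` must be a single non-negative number (seconds).")
  }
  if (nrow(x) <= 1 || max_gap == 0) return(x)
  gaps <- x$start[-1] - x$end[-nrow(x)]
  first <- which(c(TRUE, gaps >= max_gap))      # first member of each merged run
  last <- c(first[-1] - 1L, nrow(x))            # last member (ends are increasing)
  tibble(start = x$start[first], end = x$end[last])
}

#' Drop intervals shorter than a minimum duration
#'
#' Intervals with duration `>= min_duration` survive unchanged; shorter ones
#' are removed (nothing is truncated). Used for minimum bout durations
#' (e.g. 30 s sleep bouts, 2 s freezing bouts, 1.5 s standard freezing).
#'
#' @param x Interval tibble.
#' @param min_duration Minimum duration in seconds (>= 0).
#' @return Interval tibble.
#' @export
drop_short <- function(x, min_duration) {
  if (!is.numeric(min_duration) || length(min_duration) != 1 ||
      !is.finite(min_duration) || min_duration < 0) {
    stop_invalid("`min_duration` must be a single non-negative number (seconds).")
  }
  x[x$end - x$start >= min_duration, , drop = FALSE]
}

#' Set operations on interval sets
#'
#' `interval_subtract(a, b)` returns the time covered by `a` but not `b`;
#' `interval_intersect(a, b)` the time covered by both; `interval_union(a, b)`
#' the time covered by either. All return valid (sorted, disjoint) interval
#' tibbles.
#'
#' @param a,b Interval tibbles.
#' @return Interval tibble.
#' @examples
#' interval_subtract(intervals(0, 10), intervals(3, 5))
#' @export
interval_subtract <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    cut <- b[b$end > s & b$start < e, , drop = FALSE]
    cur <- s
    if (nrow(cut) > 0) {
      for (j in seq_len(nrow(cut))) {
        if (cut$start[j] > cur) {
          out_s <- c(out_s, cur); out_e <- c(out_e, cut$start[j])
        }
        cur <- max(cur, cut$end[j])
      }
    }
    if (cur < e) { out_s <- c(out_s, cur); out_e <- c(out_e, e) }
  }
  if (length(out_s) == 0) return(empty_intervals())
  intervals(out_s, out_e)
}

#' @rdname interval_subtract
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    hit <- b[b$end > a$start[i] & b$start < a$end[i], , drop = FALSE]
    if (nrow(hit) > 0) {
      out_s <- c(out_s, pmax(hit$start, a$start[i]))
      out_e <- c(out_e, pmin(hit$end, a$end[i]))
    }
  }
  if (length(out_s) == 0) return(empty_intervals())
  intervals(out_s, out_e)
}

#' @rdname interval_subtract
#' @export
interval_union <- function(a, b) {
  intervals(c(a$start, b$start), c(a$end, b$end))
}

#' Keep candidates that follow (or precede) an anchor within a delay
#'
#' With `direction = "after"`, a candidate is retained when its start lies at
#' most `max_delay` seconds after the end of some anchor; overlap with an
#' anchor counts as delay 0. With `direction = "before"`, the rule is mirrored:
#' the candidate's end must lie at most `max_delay` seconds before some
#' anchor's start. This implements the temporal nesting rules of the scoring
#' pipeline: REM epochs must follow slow-wave sleep (within ~30 s), and quiet
#' wakefulness must precede it (within ~2 min). The delay comparison is
#' inclusive (`<= max_delay`).
#'
#' @param candidates,anchors Interval tibbles.
#' @param max_delay Maximum delay in seconds (>= 0).
#' @param direction `"after"` (candidates follow anchors) or `"before"`.
#' @return The retained subset of `candidates` (each at most once).
#' @examples
#' follows_within(intervals(100, 130), intervals(0, 90), max_delay = 30)
#' @export
follows_within <- function(candidates, anchors, max_delay,
                           direction = c("after", "before")) {
  direction <- match.arg(direction)
  if (!is.numeric(max_delay) || length(max_delay) != 1 ||
      !is.finite(max_delay) || max_delay < 0) {
    stop_invalid("`max_delay` must be a single non-negative number (seconds).")
  }
  if (nrow(candidates) == 0 || nrow(anchors) == 0) {
    return(candidates[0, , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates$start[i]; e <- candidates$end[i]
    overlaps <- any(anchors$end > s & anchors$start < e)
    if (overlaps) return(TRUE)
    if (direction == "after") {
      delay <- s - anchors$end
    } else {
      delay <- anchors$start - e
    }
    any(delay >= 0 & delay <= max_delay)
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Read and write labeled interval tables
#'
#' Interval sets are serialized as TSV with columns `start_s`, `end_s`,
#' `label`, times printed with 4 decimal places.
#'
#' @param x Interval tibble; may carry a `label`/`state` column, otherwise
#'   `label` is used for every row.
#' @param path File path.
#' @param label Default label when `x` has no label column.
#' @return `write_intervals_tsv()` returns `path` invisibly;
#'   `read_intervals_tsv()` returns a tibble with columns `start`, `end`,
#'   `label`.
#' @export
write_intervals_tsv <- function(x, path, label = "epoch") {
  lab <- if ("label" %in% names(x)) x$label else if ("state" %in% names(x)) x$state else rep(label, nrow(x))
  df <- data.frame(
    start_s = sprintf("%.4f", x$start),
    end_s = sprintf("%.4f", x$end),
    label = lab
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_tsv
#' @export
read_intervals_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "numeric", "character"))
  tibble(start = df$start_s, end = df$end_s, label = df$label)
}
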
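immobile_states <- c("sws", "rem", "quiet_wake", "freezing")

#' Per-bin state labels of a labeled interval table
#'
#' Assigns each time bin (by its center) the label of the interval covering
#' it, or `"none"` when uncovered. Works for both scored output and generator
#' ground truth.
#'
#' @param states A labeled interval tibble (`start`, `end`, and `state` or
#'   `label`).
#' @param duration Session duration in seconds.
#' @param bin Bin width in seconds (default 1).
#' @return Character vector of length `floor(duration / bin)`.
#' @export
bin_labels <- function(states, duration, bin = 1) {
  lab_col <- if ("state" %in% names(states)) "state" else "label"
  n <- floor(duration / bin)
  centers <- (seq_len(n) - 0.5) * bin
  out <- rep("none", n)
  for (i in seq_len(nrow(states))) {
    hit <- centers >= states$start[i] & centers < states$end[i]
    out[hit] <- states[[lab_col]][i]
  }
  out
}

#' Agreement between a scoring and ground truth
#'
#' Compares per-bin labels over the bins whose ground-truth state is one of
#' the four immobility states. Returns the fraction of those bins where the
#' scored label matches the truth.
#'
#' @param scoring A `state_scoring` (or a labeled interval tibble).
#' @param truth Ground-truth labeled interval tibble (e.g.
#'   `generate_session()$truth`).
#' @param duration Session duration in seconds; defaults to the scoring's
#'   recorded duration.
#' @param bin Bin width in seconds.
#' @return A list with `agreement` (fraction in \[0, 1\]), `n_bins`, and the
#'   per-bin `table` (tibble with `truth`, `scored` columns).
#' @export
scoring_agreement <- function(scoring, truth, duration = NULL, bin = 1) {
  states <- if (inherits(scoring, "state_scoring")) scoring$states else scoring
  duration <- duration %||%
    (if (inherits(scoring, "state_scoring")) scoring$diagnostics$session_duration
     else max(truth$end))
  tl <- bin_labels(truth, duration, bin)
  sl <- bin_labels(states, duration, bin)
  keep <- tl %in% immobile_states
  list(
    agreement = mean(sl[keep] == tl[keep]),
    n_bins = sum(keep),
    table = tibble(truth = tl[keep], scored = sl[keep])
  )
}

#' Onset/offset error of detected epochs against ground truth
#'
#' For every ground-truth epoch boundary (onset and offset), the absolute
#' distance to the nearest detected boundary of the same kind. Used to check
#' how precisely SWS boundaries are recovered.
#'
#' @param detected,truth Interval tibbles (e.g. detected SWS and true SWS).
#' @return Numeric vector of absolute errors in seconds (length
#'   `2 * nrow(truth)`); `Inf` where nothing was detected.
#' @export
boundary_errors <- function(detected, truth) {
  if (nrow(truth) == 0) return(numeric(0))
  if (nrow(detected) == 0) return(rep(Inf, 2L * nrow(truth)))
  on_err <- vapply(truth$start, function(s) min(abs(detected$start - s)), numeric(1))
  off_err <- vapply(truth$end, function(e) min(abs(detected$end - e)), numeric(1))
  c(on_err, off_err)
}

#' Pairwise overlap between scored states
#'
#' Total pairwise intersection duration between the four state sets of a
#' scoring - exactly 0 by construction for [score_session()].
#'
#' @param scoring A `state_scoring`.
#' @return Total overlap duration in seconds.
#' @export
total_state_overlap <- function(scoring) {
  sets <- list(scoring$sws, scoring$rem, scoring$quiet_wake, scoring$freezing)
  tot <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    tot <- tot + interval_duration(interval_intersect(sets[[i]], sets[[j]]))
  }
  tot
}
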
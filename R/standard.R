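#' Standard (baseline) freezing and sleep scoring
#'
#' The conventional literature pipelines, computed independently of each other:
#' freezing is all immobility longer than 1.5 s (movements < 0.2 s ignored);
#' sleep is all immobility longer than 60 s (movements < 1 s ignored), with
#' the theta/delta ratio bins inside sleep split into two groups by k-means -
#' the high-ratio group becomes REM and the rest SWS. Because the two scorings
#' are independent, the same immobility is routinely labeled both freezing and
#' sleep; this operation exists to expose that failure mode (the 4 Hz freezing
#' rhythm sits inside the delta band, so the theta/delta ratio cannot tell
#' freezing from SWS).
#'
#' @param hpc Hippocampal (or cortical) LFP [signal_trace()] for theta/delta.
#' @param speed Speed [signal_trace()].
#' @param params A [scoring_params()] (bands, speed threshold, and the
#'   standard-specific durations below are taken from it).
#' @param freezing_min,freezing_gap,sleep_min,sleep_gap Standard-pipeline
#'   durations in seconds (defaults 1.5, 0.2, 60, 1).
#' @return A list of class `standard_scoring` with interval tibbles
#'   `freezing`, `sws`, `rem`, `sleep`, and `overlap` (freezing intersected
#'   with sleep - nonzero by construction whenever long freezing bouts exist).
#' @export
standard_score <- function(hpc, speed, params = scoring_params(),
                           freezing_min = 1.5, freezing_gap = 0.2,
                           sleep_min = 60, sleep_gap = 1) {
  thr <- params$speed_threshold %||% estimate_speed_threshold(speed)
  raw_immobility <- intervals_from_mask(speed$samples < thr, speed$rate,
                                        speed$start_time)
  freezing <- raw_immobility |>
    close_gaps(freezing_gap) |>
    drop_short(freezing_min)
  sleep <- raw_immobility |>
    close_gaps(sleep_gap) |>
    drop_short(sleep_min)
  rem <- empty_intervals()
  sws <- sleep
  if (nrow(sleep) > 0) {
    if (hpc$rate > params$analysis_rate) hpc <- decimate_lfp(hpc, params$analysis_rate)
    ratio <- band_power_ratio(hpc, params$theta_band, params$delta_band,
                              bin = params$rem_bin)
    vals <- restrict_samples(ratio, sleep, subsample = NULL)
    tr <- tryCatch(kmeans2_threshold(vals), error = function(e) NULL)
    if (!is.null(tr)) {
      supra <- intervals_from_mask(ratio$samples > tr$threshold,
                                   ratio$rate, ratio$start_time)
      rem <- interval_intersect(supra, sleep)
      sws <- interval_subtract(sleep, rem)
    }
  }
  structure(
    list(freezing = freezing, sws = sws, rem = rem, sleep = sleep,
         overlap = interval_intersect(freezing, sleep),
         speed_threshold = thr),
    class = "standard_scoring"
  )
}

#' @export
print.standard_scoring <- function(x, ...) {
  cat("<standard_scoring> (independent freezing and sleep pipelines)\n")
  cat(sprintf("  freezing %.1f s | sleep %.1f s (SWS %.1f, REM %.1f) | freezing-sleep overlap %.1f s\n",
              interval_duration(x$freezing), interval_duration(x$sleep),
              interval_duration(x$sws), interval_duration(x$rem),
              interval_duration(x$overlap)))
  invisible(x)
}
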
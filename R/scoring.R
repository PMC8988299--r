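#' Scoring parameters
#'
#' All tunable parameters of the state-scoring pipeline with their defaults:
#' spindle band 9-17 Hz, theta 6-9 Hz, delta 0.5-4 Hz; 14 s Gaussian smoothing
#' of the spindle envelope and 8 s smoothing of the cortical theta/delta
#' ratio; minimum SWS bout 30 s with movements < 1 s ignored; hippocampal REM
#' threshold 1 with REM allowed up to 30 s after SWS; quiet wakefulness up to
#' 120 s before SWS; freezing bouts >= 2 s with movements < 0.2 s ignored.
#'
#' @param speed_threshold Immobility threshold in speed units; `NULL` (default)
#'   estimates it by a two-means split of log speed.
#' @param spindle_band,theta_band,delta_band [band_definition()]s.
#' @param spindle_smooth_window Gaussian window (s) for the spindle envelope.
#' @param cortical_ratio_smooth_window Gaussian window (s) for the cortical
#'   theta/delta ratio (cortical REM mode only).
#' @param sws_min_duration,sws_max_gap Minimum SWS bout (s) and maximum ignored
#'   movement (s).
#' @param rem_ratio_threshold Fixed theta/delta threshold (hippocampal mode).
#' @param rem_max_delay_after_sws Maximum delay (s) of a REM epoch after SWS.
#' @param rem_min_duration Minimum REM candidate duration (s).
#' @param rem_bin Theta/delta ratio bin width (s).
#' @param rem_chain If `TRUE`, accepted REM epochs also anchor later REM
#'   candidates; default `FALSE` (only SWS anchors).
#' @param quiet_wake_max_lead Maximum lead (s) of quiet wakefulness before SWS.
#' @param freezing_min_duration,freezing_max_gap Minimum freezing bout (s) and
#'   maximum ignored movement (s).
#' @param immobility_min_duration,immobility_max_gap Immobility bout filter (s).
#' @param sws_effectiveness_floor Minimum separation effectiveness `m` of the
#'   spindle-power split for SWS to be declared.
#' @param sws_contrast_floor Minimum ratio of high/low spindle-power group
#'   means; below it the envelope is treated as unimodal (no sleep).
#' @param threshold_subsample Spacing (s) of envelope samples entering the
#'   k-means threshold.
#' @param threshold_on_immobility If `TRUE` (default) the SWS threshold is fit
#'   on immobility samples only; `FALSE` uses the whole session.
#' @param smooth_window_is_sd If `TRUE` (default) the smoothing windows are
#'   Gaussian standard deviations, the convention of the Matlab toolboxes this
#'   field smooths with; `FALSE` reads them as total kernel support
#'   (SD = window / 6).
#' @param analysis_rate Internal LFP analysis rate in Hz; LFP channels are
#'   decimated to this rate before filtering (all bands used are < 20 Hz).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(speed_threshold = NULL,
                           spindle_band = band_definition("spindle", 9, 17),
                           theta_band = band_definition("theta", 6, 9),
                           delta_band = band_definition("delta", 0.5, 4),
                           spindle_smooth_window = 14,
                           cortical_ratio_smooth_window = 8,
                           sws_min_duration = 30,
                           sws_max_gap = 1,
                           rem_ratio_threshold = 1,
                           rem_max_delay_after_sws = 30,
                           rem_min_duration = 5,
                           rem_bin = 1,
                           rem_chain = FALSE,
                           quiet_wake_max_lead = 120,
                           freezing_min_duration = 2,
                           freezing_max_gap = 0.2,
                           immobility_min_duration = 1.5,
                           immobility_max_gap = 0.2,
                           sws_effectiveness_floor = 0.5,
                           sws_contrast_floor = 1.5,
                           threshold_subsample = 0.5,
                           threshold_on_immobility = TRUE,
                           smooth_window_is_sd = TRUE,
                           analysis_rate = 250) {
  p <- list(
    speed_threshold = speed_threshold,
    spindle_band = check_band(spindle_band, Inf),
    theta_band = check_band(theta_band, Inf),
    delta_band = check_band(delta_band, Inf),
    spindle_smooth_window = spindle_smooth_window,
    cortical_ratio_smooth_window = cortical_ratio_smooth_window,
    sws_min_duration = sws_min_duration,
    sws_max_gap = sws_max_gap,
    rem_ratio_threshold = rem_ratio_threshold,
    rem_max_delay_after_sws = rem_max_delay_after_sws,
    rem_min_duration = rem_min_duration,
    rem_bin = rem_bin,
    rem_chain = isTRUE(rem_chain),
    quiet_wake_max_lead = quiet_wake_max_lead,
    freezing_min_duration = freezing_min_duration,
    freezing_max_gap = freezing_max_gap,
    immobility_min_duration = immobility_min_duration,
    immobility_max_gap = immobility_max_gap,
    sws_effectiveness_floor = sws_effectiveness_floor,
    sws_contrast_floor = sws_contrast_floor,
    threshold_subsample = threshold_subsample,
    threshold_on_immobility = isTRUE(threshold_on_immobility),
    smooth_window_is_sd = isTRUE(smooth_window_is_sd),
    analysis_rate = analysis_rate
  )
  durs <- c("spindle_smooth_window", "cortical_ratio_smooth_window",
            "sws_min_duration", "sws_max_gap", "rem_max_delay_after_sws",
            "rem_min_duration", "rem_bin", "quiet_wake_max_lead",
            "freezing_min_duration", "freezing_max_gap",
            "immobility_min_duration", "immobility_max_gap")
  for (d in durs) {
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1 || !is.finite(p[[d]]) || p[[d]] < 0) {
      stop_invalid(sprintf("`%s` must be a single non-negative number.", d))
    }
  }
  structure(p, class = "scoring_params")
}

#' Estimate the immobility speed threshold
#'
#' Two-means split of `log(speed + eps)`; the threshold is the boundary
#' mapped back to speed units. Used when no explicit threshold is supplied.
#'
#' @param speed A [signal_trace()] of non-negative speed values.
#' @return Threshold in speed units.
#' @export
estimate_speed_threshold <- function(speed) {
  eps <- max(1e-6, stats::quantile(speed$samples[speed$samples > 0], 0.01,
                                   names = FALSE, na.rm = TRUE) / 10)
  tr <- kmeans2_threshold(log(speed$samples + eps))
  if (diff(tr$group_means) < log(2)) {
    warn(paste(
      "Speed distribution looks unimodal (group contrast < 2x);",
      "the estimated immobility threshold is unreliable - consider",
      "supplying `speed_threshold` explicitly."
    ))
  }
  exp(tr$threshold) - eps
}

#' Detect immobility from a speed trace
#'
#' Maximal sub-threshold runs of the speed trace, with gaps shorter than
#' `immobility_max_gap` (brief movements) closed and bouts shorter than
#' `immobility_min_duration` dropped.
#'
#' @param speed A [signal_trace()] of non-negative speed values.
#' @param params A [scoring_params()].
#' @return Interval tibble of immobility bouts.
#' @export
detect_immobility <- function(speed, params = scoring_params()) {
  if (length(speed$samples) == 0) stop_invalid("Empty speed trace.")
  thr <- params$speed_threshold %||% estimate_speed_threshold(speed)
  intervals_from_mask(speed$samples < thr, speed$rate, speed$start_time) |>
    close_gaps(params$immobility_max_gap) |>
    drop_short(params$immobility_min_duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian smoothing under the params' window convention (SD vs support)
smooth_by_params <- function(x, window, params) {
  sd <- if (params$smooth_window_is_sd) window else window / 6
  gaussian_smooth(x, window, sd = sd)
}

# smoothed spindle-band envelope of a cortical trace
smoothed_spindle_power <- function(cortical, params) {
  bandpass(cortical, params$spindle_band) |>
    hilbert_envelope() |>
    smooth_by_params(params$spindle_smooth_window, params)
}

#' Detect slow-wave sleep from smoothed spindle power
#'
#' Filters the cortical LFP in the spindle band, takes the Hilbert envelope,
#' smooths it with a 14 s Gaussian window, fits a two-means threshold on the
#' immobility-restricted samples, and classifies supra-threshold immobility as
#' SWS (gaps < `sws_max_gap` closed, bouts < `sws_min_duration` dropped, and
#' the result re-intersected with immobility so gap-closing only rescues the
#' duration filter). If the spindle-power distribution shows no usable
#' bimodality (effectiveness below `sws_effectiveness_floor`, or high/low
#' group-mean contrast below `sws_contrast_floor`), no SWS is declared and a
#' warning is issued instead of an error.
#'
#' @param cortical Cortical LFP [signal_trace()].
#' @param immobility Interval tibble from [detect_immobility()].
#' @param params A [scoring_params()].
#' @return A list with `sws` (interval tibble) and `threshold`
#'   (a `threshold_result`, or `NULL` when degenerate).
#' @export
detect_sws <- function(cortical, immobility, params = scoring_params()) {
  if (nrow(immobility) == 0) {
    return(list(sws = empty_intervals(), threshold = NULL))
  }
  env <- smoothed_spindle_power(cortical, params)
  vals <- if (params$threshold_on_immobility) {
    restrict_samples(env, immobility, params$threshold_subsample)
  } else {
    env$samples[seq(1, length(env$samples),
                    by = max(1L, round(params$threshold_subsample * env$rate)))]
  }
  tr <- tryCatch(kmeans2_threshold(vals), error = function(e) NULL)
  no_sleep <- is.null(tr) ||
    tr$effectiveness < params$sws_effectiveness_floor ||
    (tr$group_means[1] > 0 &&
       tr$group_means[2] / tr$group_means[1] < params$sws_contrast_floor)
  if (no_sleep) {
    warn(paste(
      "Smoothed spindle power shows no usable bimodality during immobility;",
      "declaring no slow-wave sleep."
    ))
    return(list(sws = empty_intervals(), threshold = tr))
  }
  supra <- intervals_from_mask(env$samples > tr$threshold, env$rate, env$start_time)
  sws <- interval_intersect(supra, immobility) |>
    close_gaps(params$sws_max_gap) |>
    drop_short(params$sws_min_duration) |>
    interval_intersect(immobility)
  list(sws = sws, threshold = tr)
}

#' Detect REM sleep from the theta/delta ratio
#'
#' Within the immobility remaining after SWS, bins the theta/delta band-power
#' ratio (1 s bins) and keeps maximal supra-threshold runs of at least
#' `rem_min_duration` seconds that follow a SWS epoch within
#' `rem_max_delay_after_sws` seconds. In hippocampal mode the threshold is the
#' fixed `rem_ratio_threshold` (default 1); in cortical mode the ratio is
#' first smoothed (8 s Gaussian) and the threshold is selected by the Otsu
#' method, because the cortical theta/delta ratio runs lower than the
#' hippocampal one.
#'
#' @param lfp Hippocampal or cortical LFP [signal_trace()], per `mode`.
#' @param immobility,sws Interval tibbles.
#' @param params A [scoring_params()].
#' @param mode `"hpc"` or `"cortical"`.
#' @return A list with `rem` (interval tibble), `threshold` (numeric), and
#'   `ratio` (the binned ratio trace).
#' @export
detect_rem <- function(lfp, immobility, sws, params = scoring_params(),
                       mode = c("hpc", "cortical")) {
  mode <- match.arg(mode)
  remaining <- interval_subtract(immobility, sws)
  if (nrow(sws) == 0 || nrow(remaining) == 0) {
    return(list(rem = empty_intervals(), threshold = NA_real_, ratio = NULL))
  }
  ratio <- band_power_ratio(lfp, params$theta_band, params$delta_band,
                            bin = params$rem_bin)
  if (mode == "cortical") {
    # power ratios are multiplicative with a huge dynamic range: smooth and
    # threshold on the log scale (where the two classes are comparably
    # dispersed and Gaussian smoothing cannot smear the high mode across
    # minutes of low-ratio sleep), then report the cut in ratio units
    ratio$samples <- log(pmax(ratio$samples, .Machine$double.xmin))
    ratio <- smooth_by_params(ratio, params$cortical_ratio_smooth_window, params)
    vals <- restrict_samples(ratio, remaining, subsample = NULL)
    vals <- vals[is.finite(vals)]
    tr <- tryCatch(otsu_threshold(vals), error = function(e) NULL)
    if (is.null(tr)) {
      warn("Degenerate cortical theta/delta distribution; no REM detected.")
      return(list(rem = empty_intervals(), threshold = NA_real_, ratio = ratio))
    }
    supra_mask <- ratio$samples > tr$threshold
    thr <- exp(tr$threshold)
    ratio$samples <- exp(ratio$samples)   # expose the smoothed ratio in ratio units
  } else {
    thr <- params$rem_ratio_threshold
    supra_mask <- ratio$samples > thr
  }
  supra <- intervals_from_mask(supra_mask, ratio$rate, ratio$start_time)
  candidates <- interval_intersect(supra, remaining) |>
    close_gaps(params$rem_bin + 1e-9) |>   # rejoin runs split by bin edges
    drop_short(params$rem_min_duration)
  if (params$rem_chain) {
    # accepted REM epochs may anchor later candidates (REM chains off REM)
    anchors <- sws
    repeat {
      kept <- follows_within(candidates, anchors,
                             params$rem_max_delay_after_sws, "after")
      new_anchors <- interval_union(sws, kept)
      if (interval_duration(new_anchors) == interval_duration(anchors)) break
      anchors <- new_anchors
    }
    rem <- kept
  } else {
    rem <- follows_within(candidates, sws, params$rem_max_delay_after_sws, "after")
  }
  list(rem = interval_intersect(rem, remaining), threshold = thr, ratio = ratio)
}

#' Detect quiet wakefulness
#'
#' From the immobility not classified as sleep, keeps the epochs whose end
#' lies within `quiet_wake_max_lead` seconds before the start of some SWS
#' epoch: animals readjust before falling asleep, so immobility leading into
#' SWS is waking rest rather than freezing.
#'
#' @param immobility,sws,rem Interval tibbles.
#' @param params A [scoring_params()].
#' @return Interval tibble of quiet wakefulness.
#' @export
detect_quiet_wake <- function(immobility, sws, rem, params = scoring_params()) {
  remainder <- interval_subtract(immobility, interval_union(sws, rem))
  if (nrow(remainder) == 0 || nrow(sws) == 0) return(empty_intervals())
  follows_within(remainder, sws, params$quiet_wake_max_lead, "before")
}

#' Detect freezing as the remaining immobility
#'
#' All immobility not classified as SWS, REM, or quiet wakefulness is scored
#' as freezing, with interruptions < `freezing_max_gap` ignored and bouts
#' < `freezing_min_duration` dropped. The gap-closed result is re-subtracted
#' from the other states, so the zero-overlap guarantee holds by construction;
#' brief movement interruptions are kept inside freezing bouts, as is
#' conventional for freezing scoring.
#'
#' @param immobility,sws,rem,quiet_wake Interval tibbles.
#' @param params A [scoring_params()].
#' @return Interval tibble of freezing bouts.
#' @export
detect_freezing <- function(immobility, sws, rem, quiet_wake,
                            params = scoring_params()) {
  others <- interval_union(interval_union(sws, rem), quiet_wake)
  remainder <- interval_subtract(immobility, others)
  if (nrow(remainder) == 0) return(empty_intervals())
  close_gaps(remainder, params$freezing_max_gap) |>
    interval_subtract(others) |>
    drop_short(params$freezing_min_duration)
}

#' Score a session into SWS, REM, quiet wakefulness, and freezing
#'
#' Runs the full pipeline: immobility from the speed trace, SWS from smoothed
#' cortical spindle power, REM from the theta/delta ratio (hippocampal LFP
#' when provided, cortical fallback otherwise), quiet wakefulness as the
#' immobility leading into SWS, and freezing as the remainder. The four state
#' sets are pairwise disjoint and contained in immobility by construction.
#'
#' @param cortical Cortical LFP [signal_trace()].
#' @param speed Speed [signal_trace()] (e.g. IMU angular speed).
#' @param hpc Optional hippocampal LFP [signal_trace()]; selects the REM mode.
#' @param params A [scoring_params()].
#' @param mode REM mode override; default auto (`"hpc"` if `hpc` given).
#' @return An object of class `state_scoring`: list with `states` (tibble
#'   `start`, `end`, `state`), per-state interval tibbles (`sws`, `rem`,
#'   `quiet_wake`, `freezing`), `immobility`, `diagnostics`, and `params`.
#'   Use [generics::tidy()], [generics::glance()], and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' \donttest{
#' ses <- generate_session(state_plan(
#'   c("active", "quiet_wake", "sws", "rem", "active", "freezing"),
#'   c(60, 40, 180, 50, 40, 90)
#' ), seed = 1)
#' sc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
#' generics::glance(sc)
#' }
#' @export
score_session <- function(cortical, speed, hpc = NULL,
                          params = scoring_params(), mode = NULL) {
  stopifnot(inherits(cortical, "signal_trace"), inherits(speed, "signal_trace"))
  check_alignment(cortical, speed)
  if (!is.null(hpc)) check_alignment(cortical, hpc)
  mode <- mode %||% if (!is.null(hpc)) "hpc" else "cortical"
  if (mode == "hpc" && is.null(hpc)) {
    stop_invalid("REM mode 'hpc' requires a hippocampal trace.")
  }
  if (cortical$rate > params$analysis_rate) {
    cortical <- decimate_lfp(cortical, params$analysis_rate)
  }
  if (!is.null(hpc) && hpc$rate > params$analysis_rate) {
    hpc <- decimate_lfp(hpc, params$analysis_rate)
  }
  speed_thr <- params$speed_threshold %||% estimate_speed_threshold(speed)
  p <- params; p$speed_threshold <- speed_thr
  immobility <- detect_immobility(speed, p)
  sws_res <- detect_sws(cortical, immobility, p)
  rem_lfp <- if (mode == "hpc") hpc else cortical
  rem_res <- detect_rem(rem_lfp, immobility, sws_res$sws, p, mode = mode)
  quiet_wake <- detect_quiet_wake(immobility, sws_res$sws, rem_res$rem, p)
  freezing <- detect_freezing(immobility, sws_res$sws, rem_res$rem, quiet_wake, p)
  sets <- list(sws = sws_res$sws, rem = rem_res$rem,
               quiet_wake = quiet_wake, freezing = freezing)
  states <- purrr::imap_dfr(sets, function(iv, nm) {
    if (nrow(iv) == 0) return(tibble(start = numeric(), end = numeric(),
                                     state = character()))
    mutate(iv, state = nm)
  }) |> arrange(.data$start)
  structure(
    list(
      states = states,
      sws = sets$sws, rem = sets$rem,
      quiet_wake = sets$quiet_wake, freezing = sets$freezing,
      immobility = immobility,
      diagnostics = list(
        mode = mode,
        speed_threshold = speed_thr,
        sws_threshold = sws_res$threshold,
        rem_threshold = rem_res$threshold,
        session_duration = trace_duration(speed)
      ),
      params = p
    ),
    class = "state_scoring"
  )
}

check_alignment <- function(a, b) {
  if (abs(a$start_time - b$start_time) > 1e-9 ||
      abs(trace_duration(a) - trace_duration(b)) > 1) {
    abort("Traces are not time-aligned (common start, durations equal within 1 s).",
          class = "spindlescore_alignment_error")
  }
  invisible(TRUE)
}

#' @export
print.state_scoring <- function(x, ...) {
  cat("<state_scoring>\n")
  cat(sprintf("  session: %.1f s, immobility %.1f s, REM mode '%s'\n",
              x$diagnostics$session_duration,
              interval_duration(x$immobility), x$diagnostics$mode))
  for (s in c("sws", "rem", "quiet_wake", "freezing")) {
    cat(sprintf("  %-10s %6.1f s in %d bouts\n", s,
                interval_duration(x[[s]]), nrow(x[[s]])))
  }
  invisible(x)
}
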
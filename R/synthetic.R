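#' Synthetic session recipe
#'
#' Parameters of the seeded session generator. Each behavioral state has an
#' oscillation recipe per channel (cortical / hippocampal): a set of
#' `(freq Hz, amp)` sinusoidal components plus broadband Gaussian noise.
#' Slow-wave sleep additionally receives Poisson-placed spindle bursts on the
#' cortical channel. Defaults emulate rodent physiology: SWS = 1.5 Hz delta
#' (amp 1.0) with 12 Hz spindle bursts (amp 0.8, 0.7 s, 0.25 bursts/s);
#' freezing = 4 Hz rhythm (amp 1.0, no spindles); REM = 7.5 Hz theta; noise
#' SD 0.2. Speed traces sit well below (immobile states) or above (active)
#' the immobility threshold, with optional brief movement spikes that exercise
#' gap-closing.
#'
#' @param lfp_rate,motion_rate Sampling rates in Hz (defaults 1250 and 300).
#' @param noise_sd Broadband noise SD added to both LFP channels.
#' @param spindle_freq,spindle_amp,spindle_duration,spindle_rate Spindle burst
#'   parameters (Hz, amplitude, s, bursts/s).
#' @param speed_active_level,speed_active_sd Active-state speed level and SD.
#' @param speed_immobile_sd Immobile speed noise SD (half-normal).
#' @param speed_spike_rate Rate (spikes/s) of brief 0.1-0.2 s movement spikes
#'   inside immobile states.
#' @param speed_threshold The immobility threshold the speed levels are
#'   designed around (used by the generator, echoed for convenience).
#' @param cortical,hpc Named lists (by state) of component tibbles
#'   (`freq`, `amp`); override to change the oscillatory recipes.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(lfp_rate = 1250, motion_rate = 300, noise_sd = 0.2,
                         spindle_freq = 12, spindle_amp = 0.8,
                         spindle_duration = 0.7, spindle_rate = 0.25,
                         speed_active_level = 3, speed_active_sd = 0.3,
                         speed_immobile_sd = 0.12, speed_spike_rate = 0.02,
                         speed_threshold = 1,
                         cortical = NULL, hpc = NULL) {
  comp <- function(freq, amp) tibble(freq = freq, amp = amp)
  cortical <- cortical %||% list(
    active = comp(7.5, 0.3),
    quiet_wake = comp(2, 0.3),
    sws = comp(1.5, 1.0),                 # spindle bursts added separately
    rem = comp(c(7.5, 1.5), c(0.6, 0.15)),
    freezing = comp(4, 1.0)
  )
  hpc <- hpc %||% list(
    active = comp(7.5, 1.0),
    quiet_wake = comp(c(2, 7.5), c(0.5, 0.2)),
    sws = comp(c(1.5, 7.5), c(1.2, 0.1)),
    rem = comp(c(7.5, 1.5), c(1.0, 0.2)),
    freezing = comp(c(4, 7.5), c(0.8, 0.1))
  )
  structure(
    list(lfp_rate = lfp_rate, motion_rate = motion_rate, noise_sd = noise_sd,
         spindle_freq = spindle_freq, spindle_amp = spindle_amp,
         spindle_duration = spindle_duration, spindle_rate = spindle_rate,
         speed_active_level = speed_active_level,
         speed_active_sd = speed_active_sd,
         speed_immobile_sd = speed_immobile_sd,
         speed_spike_rate = speed_spike_rate,
         speed_threshold = speed_threshold,
         cortical = cortical, hpc = hpc),
    class = "synth_params"
  )
}

synth_states <- c("active", "quiet_wake", "sws", "rem", "freezing")

#' Planned state timeline for a synthetic session
#'
#' @param states Character vector of state labels (subset of `active`,
#'   `quiet_wake`, `sws`, `rem`, `freezing`).
#' @param durations Segment durations in seconds (> 0), same length.
#' @param physiological If `TRUE`, every `rem` segment must directly follow a
#'   `sws` segment (REM nests within sleep cycles).
#' @return A tibble with columns `state`, `duration`, `start`, `end`.
#' @examples
#' state_plan(c("active", "sws", "rem"), c(60, 180, 60))
#' @export
state_plan <- function(states, durations, physiological = TRUE) {
  states <- as.character(states)
  if (length(states) != length(durations) || length(states) == 0) {
    stop_invalid("`states` and `durations` must be non-empty and equal length.")
  }
  if (!all(states %in% synth_states)) {
    stop_invalid(sprintf("Unknown state(s): %s",
                         paste(setdiff(states, synth_states), collapse = ", ")))
  }
  if (!all(is.finite(durations)) || any(durations <= 0)) {
    stop_invalid("All durations must be positive and finite.")
  }
  if (physiological) {
    bad <- which(states == "rem" & (seq_along(states) == 1 |
                                      c("", head(states, -1)) != "sws"))
    if (length(bad) > 0) {
      stop_invalid("Under the physiological constraint, REM segments must directly follow SWS.")
    }
  }
  ends <- cumsum(durations)
  tibble(state = states, duration = as.numeric(durations),
         start = c(0, head(ends, -1)), end = ends)
}

#' Random mixed state plan
#'
#' Draws a session plan (~`total` seconds) composed of rest blocks
#' (active, quiet wakefulness, SWS, optionally REM + more SWS) and fear blocks
#' (active then freezing), so freezing is always bracketed by locomotion and
#' REM always follows SWS. A rest block that follows freezing starts with a
#' longer active stretch (150-300 s): animals do not fall asleep out of their
#' freezing posture, and post-arousal sleep latency runs to minutes, so quiet
#' wakefulness - not freezing - is the immobility that immediately precedes
#' sleep.
#'
#' @param seed Integer seed.
#' @param total Approximate session duration in seconds.
#' @param rem_prob Probability that a rest block contains a REM episode.
#' @return A `state_plan` tibble.
#' @export
random_state_plan <- function(seed, total = 1800, rem_prob = 0.7) {
  set.seed(seed)
  states <- character(0); durs <- numeric(0)
  t <- 0
  while (t < total) {
    after_freezing <- length(states) > 0 && tail(states, 1) == "freezing"
    if (runif(1) < 0.5) {
      s <- c("active", "quiet_wake", "sws")
      active_dur <- if (after_freezing) runif(1, 150, 300) else runif(1, 30, 120)
      d <- c(active_dur, runif(1, 30, 90), runif(1, 120, 300))
      if (runif(1) < rem_prob) {
        s <- c(s, "rem", "sws")
        d <- c(d, runif(1, 40, 90), runif(1, 60, 180))
      }
    } else {
      s <- c("active", "freezing")
      d <- c(runif(1, 30, 120), runif(1, 60, 240))
    }
    states <- c(states, s); durs <- c(durs, d)
    t <- t + sum(d)
  }
  state_plan(states, durs)
}

#' Poisson train of Hann-windowed spindle bursts
#'
#' Bursts are placed by a homogeneous Poisson process (expected count =
#' `duration * rate_hz`); each burst is a Hann-windowed sinusoid of the given
#' frequency, amplitude, and duration. Overlapping bursts add.
#'
#' @param duration Trace duration in seconds.
#' @param rate_hz Burst rate in bursts/second (>= 0).
#' @param burst_dur Burst duration in seconds.
#' @param freq Carrier frequency in Hz.
#' @param amp Peak amplitude of a single burst.
#' @param rate Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return A [signal_trace()].
#' @export
make_spindle_burst_train <- function(duration, rate_hz, burst_dur = 0.7,
                                     freq = 12, amp = 0.8, rate = 1250,
                                     seed = NULL) {
  if (rate_hz < 0) stop_invalid("`rate_hz` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate)
  out <- numeric(n)
  if (rate_hz > 0) {
    n_bursts <- rpois(1, duration * rate_hz)
    if (n_bursts > 0) {
      starts <- runif(n_bursts, 0, max(duration - burst_dur, 0))
      nb <- round(burst_dur * rate)
      tt <- (0:(nb - 1)) / rate
      hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nb)))
      for (s in starts) {
        i0 <- floor(s * rate) + 1L
        idx <- i0:min(i0 + nb - 1L, n)
        phase <- runif(1, 0, 2 * pi)
        out[idx] <- out[idx] +
          (amp * hann * sin(2 * pi * freq * tt + phase))[seq_along(idx)]
      }
    }
  }
  signal_trace(out, rate, 0)
}

render_channel <- function(plan, recipes, sp, spindles = FALSE) {
  rate <- sp$lfp_rate
  n_total <- round(sum(plan$duration) * rate)
  out <- rnorm(n_total, 0, sp$noise_sd)
  for (i in seq_len(nrow(plan))) {
    i0 <- round(plan$start[i] * rate) + 1L
    i1 <- round(plan$end[i] * rate)
    if (i1 > n_total) i1 <- n_total
    idx <- i0:i1
    tt <- (idx - 1) / rate
    rec <- recipes[[plan$state[i]]]
    if (!is.null(rec) && nrow(rec) > 0) {
      for (j in seq_len(nrow(rec))) {
        out[idx] <- out[idx] +
          rec$amp[j] * sin(2 * pi * rec$freq[j] * tt + runif(1, 0, 2 * pi))
      }
    }
    if (spindles && plan$state[i] == "sws" && sp$spindle_rate > 0) {
      train <- make_spindle_burst_train(
        duration = (i1 - i0 + 1) / rate, rate_hz = sp$spindle_rate,
        burst_dur = sp$spindle_duration, freq = sp$spindle_freq,
        amp = sp$spindle_amp, rate = rate
      )
      out[idx] <- out[idx] + train$samples[seq_along(idx)]
    }
  }
  signal_trace(out, rate, 0)
}

render_speed <- function(plan, sp) {
  rate <- sp$motion_rate
  n_total <- round(sum(plan$duration) * rate)
  out <- numeric(n_total)
  for (i in seq_len(nrow(plan))) {
    i0 <- round(plan$start[i] * rate) + 1L
    i1 <- min(round(plan$end[i] * rate), n_total)
    idx <- i0:i1
    if (plan$state[i] == "active") {
      out[idx] <- pmax(sp$speed_active_level + rnorm(length(idx), 0, sp$speed_active_sd),
                       sp$speed_threshold * 1.2)
    } else {
      out[idx] <- abs(rnorm(length(idx), 0, sp$speed_immobile_sd))
      # brief movement spikes (0.1-0.2 s) to exercise gap-closing
      seg_dur <- plan$duration[i]
      n_spikes <- rpois(1, sp$speed_spike_rate * seg_dur)
      if (n_spikes > 0) {
        margin <- 2  # keep spikes away from segment edges
        if (seg_dur > 2 * margin + 0.2) {
          at <- runif(n_spikes, margin, seg_dur - margin - 0.2)
          for (a in at) {
            dur <- runif(1, 0.1, 0.2)
            j0 <- i0 + floor(a * rate)
            j1 <- min(j0 + round(dur * rate) - 1L, i1)
            out[j0:j1] <- sp$speed_active_level
          }
        }
      }
    }
  }
  signal_trace(out, rate, 0)
}

#' Generate a complete synthetic session
#'
#' Renders cortical and hippocampal LFP traces, a speed trace, and the ground
#' truth state timeline for a planned session, deterministically for a given
#' seed. Each state contributes its designed oscillations (see
#' [synth_params()]); SWS adds Poisson spindle bursts on the cortical channel;
#' immobile states emit sub-threshold speed with occasional brief movement
#' spikes; transitions are hard segment boundaries.
#'
#' @param plan A [state_plan()] tibble.
#' @param sp A [synth_params()].
#' @param seed Integer seed; the whole session is a deterministic function of
#'   `(plan, sp, seed)`.
#' @return A list with `cortical`, `hpc`, `speed` ([signal_trace()]s), `truth`
#'   (the plan as a labeled interval tibble `start`, `end`, `state`), and
#'   `plan`.
#' @export
generate_session <- function(plan, sp = synth_params(), seed = 1) {
  if (!all(c("state", "duration", "start", "end") %in% names(plan))) {
    stop_invalid("`plan` must be a state_plan() tibble.")
  }
  set.seed(seed)
  cortical <- render_channel(plan, sp$cortical, sp, spindles = TRUE)
  hpc <- render_channel(plan, sp$hpc, sp, spindles = FALSE)
  speed <- render_speed(plan, sp)
  list(
    cortical = cortical, hpc = hpc, speed = speed,
    truth = select(plan, "start", "end", "state"),
    plan = plan
  )
}

#' Bimodality of smoothed spindle power across immobility
#'
#' Generates mixed SWS/freezing sessions, pools the smoothed spindle-band
#' envelope samples during immobility, and reports the two-means group means
#' and separation effectiveness `m`. With the default recipe the pooled
#' distribution is strongly bimodal (high mode = SWS, low mode = freezing and
#' quiet rest); zeroing the spindle amplitude collapses it toward a unimodal
#' noise floor.
#'
#' @param sp A [synth_params()].
#' @param n_sessions Number of sessions to pool (>= 1).
#' @param seed Integer seed.
#' @param params A [scoring_params()] (spindle band and smoothing window).
#' @param states Immobility classes mixed into each session (default SWS and
#'   freezing); a single class triggers a one-sided-distribution warning.
#' @return A list with `group_means`, `m`, `threshold`, `n_values`, and
#'   `values` (the pooled sample).
#' @export
bimodality_demo <- function(sp = synth_params(), n_sessions = 10, seed = 1,
                            params = scoring_params(),
                            states = c("sws", "freezing")) {
  if (n_sessions < 1) stop_invalid("`n_sessions` must be >= 1.")
  if (length(setdiff(c("sws", "freezing"), states)) > 0) {
    warn("Sessions contain a single immobility class; distribution is one-sided.")
  }
  set.seed(seed)
  seeds <- sample.int(1e6, n_sessions)
  pooled <- numeric(0)
  for (i in seq_len(n_sessions)) {
    plan <- state_plan(
      as.vector(rbind("active", states)),
      as.vector(rbind(30, runif(length(states), 200, 300)))
    )
    ses <- generate_session(plan, sp, seed = seeds[i])
    cort <- if (ses$cortical$rate > params$analysis_rate) {
      decimate_lfp(ses$cortical, params$analysis_rate)
    } else ses$cortical
    env <- smoothed_spindle_power(cort, params)
    immobility <- detect_immobility(ses$speed, local_params(params, sp))
    pooled <- c(pooled, restrict_samples(env, immobility, params$threshold_subsample))
  }
  tr <- kmeans2_threshold(pooled)
  list(group_means = tr$group_means, m = tr$effectiveness,
       threshold = tr$threshold, n_values = length(pooled), values = pooled)
}

# scoring params with the generator's designed speed threshold filled in
local_params <- function(params, sp) {
  params$speed_threshold <- params$speed_threshold %||% sp$speed_threshold
  params
}
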
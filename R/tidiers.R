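#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a scored session into a labeled interval tibble
#'
#' @param x A `state_scoring`.
#' @param ... Unused.
#' @return A tibble with columns `start`, `end`, `duration`, `state`, one row
#'   per scored epoch, ordered by start time.
#' @export
tidy.state_scoring <- function(x, ...) {
  x$states |> mutate(duration = .data$end - .data$start) |>
    select("start", "end", "duration", "state")
}

#' One-row summary of a scored session
#'
#' @param x A `state_scoring`.
#' @param ... Unused.
#' @return A one-row tibble: session and immobility durations, per-state total
#'   durations, REM mode, and the thresholds/effectiveness used.
#' @export
glance.state_scoring <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    duration_s = d$session_duration,
    immobility_s = interval_duration(x$immobility),
    sws_s = interval_duration(x$sws),
    rem_s = interval_duration(x$rem),
    quiet_wake_s = interval_duration(x$quiet_wake),
    freezing_s = interval_duration(x$freezing),
    mode = d$mode,
    speed_threshold = d$speed_threshold,
    sws_threshold = if (is.null(d$sws_threshold)) NA_real_ else d$sws_threshold$threshold,
    sws_effectiveness = if (is.null(d$sws_threshold)) NA_real_ else d$sws_threshold$effectiveness,
    rem_threshold = d$rem_threshold
  )
}

#' @export
tidy.threshold_result <- function(x, ...) {
  tibble(
    method = x$method, threshold = x$threshold,
    mean_low = x$group_means[1], mean_high = x$group_means[2],
    n_low = x$sizes[1], n_high = x$sizes[2],
    effectiveness = x$effectiveness
  )
}

#' @export
tidy.standard_scoring <- function(x, ...) {
  bind_rows(
    mutate(x$freezing, state = "freezing"),
    mutate(x$sws, state = "sws"),
    mutate(x$rem, state = "rem")
  ) |> arrange(.data$start) |>
    mutate(duration = .data$end - .data$start) |>
    select("start", "end", "duration", "state")
}

#' @export
glance.standard_scoring <- function(x, ...) {
  tibble(
    freezing_s = interval_duration(x$freezing),
    sleep_s = interval_duration(x$sleep),
    sws_s = interval_duration(x$sws),
    rem_s = interval_duration(x$rem),
    freezing_sleep_overlap_s = interval_duration(x$overlap),
    speed_threshold = x$speed_threshold
  )
}
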
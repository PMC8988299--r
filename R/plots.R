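state_palette <- c(
  sws = "#3366cc", rem = "#e6b800", quiet_wake = "#33a02c",
  freezing = "#d62728", immobility = "grey80"
)

#' Hypnogram of a scored session
#'
#' Immobility as a grey band with the four scored states as colored blocks,
#' time on the x axis.
#'
#' @param object A `state_scoring`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_scoring <- function(object, ...) {
  imm <- mutate(object$immobility, state = "immobility")
  df <- bind_rows(imm, object$states) |>
    mutate(
      ymin = ifelse(.data$state == "immobility", 0, 1),
      ymax = ifelse(.data$state == "immobility", 0.9, 2)
    )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$state
    )) +
    ggplot2::scale_fill_manual(values = state_palette) +
    ggplot2::scale_y_continuous(
      breaks = c(0.45, 1.5), labels = c("immobility", "state")
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wavelet spectrogram
#'
#' @param pow A matrix from [wavelet_spectrogram()].
#' @param max_points Cap on plotted time points (the matrix is thinned in
#'   time to stay under this).
#' @return A ggplot object.
#' @export
plot_wavelet_spectrogram <- function(pow, max_points = 2000) {
  times <- attr(pow, "times")
  freqs <- attr(pow, "freqs")
  step <- max(1L, ceiling(ncol(pow) / max_points))
  idx <- seq(1L, ncol(pow), by = step)
  df <- tidyr::expand_grid(freq = freqs, time = times[idx])
  df$power <- as.vector(t(pow[, idx, drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power") +
    ggplot2::theme_minimal()
}
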
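#' Plot an intensity contour
#'
#' @param object An [intensity_contour()] tibble.
#' @param ... Unused.
#' @return A ggplot: intensity (dB) over time.
#' @exportS3Method ggplot2::autoplot
autoplot.intensity_contour <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Intensity (dB)") +
    ggplot2::theme_minimal()
}

#' Plot an interval series
#'
#' Histogram of the interval values; for pooled IOI/IPI series the
#' two-timescale bout structure shows up as a dense within-bout mode plus a
#' long between-bout tail.
#'
#' @param object An [interval_series()].
#' @param bins Number of histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.interval_series <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value_ms)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30", colour = "white") +
    ggplot2::labs(x = paste0(series_kind(object), " (ms)"), y = "Count") +
    ggplot2::theme_minimal()
}

#' Plot a waveform
#'
#' Amplitude over time, decimated to at most `max_points` samples for
#' display.
#'
#' @param object A [waveform()].
#' @param max_points Decimation target (default 20000).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.waveform <- function(object, max_points = 20000, ...) {
  n <- length(object$samples)
  idx <- if (n > max_points) round(seq(1, n, length.out = max_points)) else seq_len(n)
  d <- tibble(time = (idx - 1) / object$rate, amplitude = object$samples[idx])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude") +
    ggplot2::theme_minimal()
}

#' Compare two interval distributions as ECDFs
#'
#' Overlays the empirical cumulative distribution functions of two interval
#' series — the visual counterpart of the Kolmogorov–Smirnov D statistic,
#' which is the largest vertical distance between the two curves.
#'
#' @param a,b [interval_series()] objects.
#' @return A ggplot.
#' @export
plot_ecdf_pair <- function(a, b) {
  d <- bind_rows(
    tibble(value_ms = a$value_ms, series = series_kind(a)),
    tibble(value_ms = b$value_ms, series = series_kind(b))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value_ms, colour = .data$series)) +
    ggplot2::stat_ecdf(linewidth = 0.5) +
    ggplot2::labs(x = "Interval (ms)", y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}
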
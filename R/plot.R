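# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_hline geom_step labs scale_y_log10 theme_minimal annotate
NULL

#' @export
ggplot2::autoplot

#' Plot a GC track
#'
#' @param object A [gc_track()].
#' @param baseline Optional baseline GC to draw as a reference line.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot gc_track
#' @export
autoplot.gc_track <- function(object, baseline = NULL, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot(df, aes(x = .data$mid, y = .data$gc)) +
    geom_line(colour = "grey30") +
    labs(x = "position (bp)", y = "GC fraction") +
    theme_minimal()
  if (!is.null(baseline)) {
    p <- p + geom_hline(yintercept = baseline, linetype = 2, colour = "red")
  }
  p
}

#' Plot a coverage track with optional islands
#'
#' @param object A [coverage_track()].
#' @param islands Optional island tibble from [detect_islands()], shaded.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, islands = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$bin_start, y = .data$depth)) +
    geom_step(colour = "steelblue") +
    labs(x = "position (bp)", y = "mean depth per bin") +
    theme_minimal()
  if (!is.null(islands) && nrow(islands)) {
    p <- p + geom_rect(
      data = as_tibble(islands),
      aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.2,
      inherit.aes = FALSE)
  }
  p
}

#' Plot a growth series with its fitted exponential window
#'
#' @param object A `growth_fit` from [fit_exponential()].
#' @param ... Ignored.
#' @return A ggplot (log10 count scale).
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$series
  p <- ggplot(df, aes(x = .data$time_h, y = .data$count)) +
    geom_point() +
    scale_y_log10() +
    labs(x = "time (h)", y = "cells per ml") +
    theme_minimal()
  if (!is.na(object$mu)) {
    w <- df[df$time_h >= object$window[1] & df$time_h <= object$window[2] &
              df$count > 0, ]
    pred <- exp(stats::predict(object$model))
    p <- p + geom_line(data = tibble(time_h = w$time_h, count = pred),
                       aes(x = .data$time_h, y = .data$count),
                       colour = "firebrick")
  }
  p
}

#' Histogram of lineage relative abundance across a survey
#'
#' @param samples Survey tibble with `cry1a_pct`.
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot.
#' @export
plot_survey <- function(samples, binwidth = 5) {
  ggplot(as_tibble(samples), aes(x = .data$cry1a_pct)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40",
                            colour = "white", boundary = 0) +
    labs(x = "lineage % of HNF", y = "samples") +
    theme_minimal()
}
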
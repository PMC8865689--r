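#' Plot growth curves, optionally marking extracted peaks
#'
#' @param plate Plate time-series tibble ([read_plate_timeseries()]).
#' @param peaks Optional [extract_peaks()] output; peak points are marked.
#' @param colour_by Layout column used for the colour scale.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(plate, peaks = NULL, colour_by = "treatment") {
  p <- ggplot2::ggplot(
    plate,
    ggplot2::aes(x = .data$time_min, y = .data$od600,
                 group = .data$well_id, colour = .data[[colour_by]])
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (min)", y = "OD600", colour = colour_by)
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$peak_time_min, y = .data$peak_od,
                   group = .data$well_id),
      shape = 4, size = 2, show.legend = FALSE
    )
  }
  p
}

#' Plot percent survival against exposure duration
#'
#' Log10 percent survival per stratum, with censored observations drawn
#' as asterisks at their LOD-implied values.
#'
#' @param survival Survival table ([survival_table()]).
#' @param stratum Column used for colour (default `"level"`).
#' @return A ggplot, faceted by stressor when several are present.
#' @export
plot_survival <- function(survival, stratum = "level") {
  p <- ggplot2::ggplot(
    survival,
    ggplot2::aes(x = .data$duration_min, y = .data$log10_percent,
                 colour = factor(.data[[stratum]]),
                 shape = .data$censored)
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                guide = "none") +
    ggplot2::labs(x = "duration (min)", y = "log10 percent survival",
                  colour = stratum)
  if (length(unique(survival$stressor)) > 1) {
    p <- p + ggplot2::facet_wrap(~stressor, scales = "free")
  }
  p
}
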
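#' Plot the per-country change scatter
#'
#' Absolute national change against absolute gap change, one point per
#' country, coloured by end-year national level when available; dashed
#' zero lines separate the four progress quadrants.
#'
#' @param scatter Output of [export_change_scatter()].
#' @return A ggplot object.
#' @export
plot_change_scatter <- function(scatter) {
  p <- ggplot2::ggplot(scatter, ggplot2::aes(
    x = .data$national_change, y = .data$gap_change
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(
      x = "Change in national no-DTP prevalence, pp",
      y = "Change in subnational 5th-95th percentile gap, pp"
    ) +
    ggplot2::theme_minimal()
  if (any(!is.na(scatter$national_end))) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$national_end),
                            size = 2) +
      ggplot2::scale_colour_viridis_c(name = "National no-DTP,\nend year (%)")
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot phase-plane trajectories
#'
#' National no-DTP prevalence (x) against the subnational gap (y), one path
#' per entity ordered by year; the lower-left corner is the equitable
#' low-level / low-gap target. Highlighted entities are coloured, the rest
#' drawn in light grey.
#'
#' @param trajectories Output of [export_phase_trajectories()].
#' @param id Entity column name.
#' @return A ggplot object.
#' @export
plot_phase_trajectories <- function(trajectories, id = "country") {
  bg <- trajectories[trajectories$highlight == "other", , drop = FALSE]
  fg <- trajectories[trajectories$highlight != "other", , drop = FALSE]
  p <- ggplot2::ggplot(mapping = ggplot2::aes(
    x = .data$national_no_dtp, y = .data$gap, group = .data[[id]]
  )) +
    ggplot2::geom_path(data = bg, colour = "grey80") +
    ggplot2::labs(
      x = "National no-DTP prevalence (%)",
      y = "Subnational 5th-95th percentile gap, pp"
    ) +
    ggplot2::theme_minimal()
  if (nrow(fg)) {
    p <- p +
      ggplot2::geom_path(data = fg,
                         ggplot2::aes(colour = .data$highlight)) +
      ggplot2::geom_point(data = fg,
                          ggplot2::aes(colour = .data$highlight), size = 1) +
      ggplot2::scale_colour_brewer(name = NULL, palette = "Dark2")
  }
  p
}
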
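#' Plot a spatial interaction curve with its simultaneous band
#'
#' @param band A [sic_band()] (or [simultaneous_band()]) tibble.
#' @param rug_zero Draw the zero reference line (default `TRUE`).
#' @return A ggplot object: mean curve with the simultaneous credible
#'   ribbon over distance.
#' @export
plot_sic_band <- function(band, rug_zero = TRUE) {
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.7) +
    ggplot2::labs(x = "distance (µm)", y = "SIC (log-intensity)") +
    ggplot2::theme_minimal()
  if (rug_zero) {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2,
                                 colour = "red3")
  }
  if (all(c("source", "target", "unit") %in% names(band))) {
    p <- p + ggplot2::ggtitle(sprintf(
      "%s → %s (%s %s)", band$source[1], band$target[1],
      band$level[1], band$unit[1]))
  }
  p
}

#' @export
autoplot.sic_fit <- function(object, level_tag = "cohort", unit = NULL,
                             source = NULL, prob = 0.95, ...) {
  plot_sic_band(sic_band(object, level_tag, unit = unit,
                         source = source, prob = prob))
}

#' @export
autoplot.sic_envelope <- function(object, ...) {
  if (isTRUE(object$untestable)) {
    stop("Envelope result is untestable; nothing to plot.", call. = FALSE)
  }
  df <- tibble::tibble(r = object$r, observed = object$observed,
                       theo = object$theo, lower = object$lower,
                       upper = object$upper)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$theo), linetype = 2,
                       colour = "red3") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "r (µm)",
                  y = sprintf("%s summary", object$statistic),
                  title = sprintf("global CSR envelope (n_sim = %d)%s",
                                  object$n_sim,
                                  if (isTRUE(object$rejected)) " - rejected"
                                  else "")) +
    ggplot2::theme_minimal()
}

#' Plot a simulated or observed study as point patterns
#'
#' @param study A [sic_study()].
#' @param images Optional subset of image ids to show.
#' @return A ggplot object faceted by image, coloured by cell type.
#' @export
plot_study <- function(study, images = NULL) {
  cells <- study$cells
  if (!is.null(images)) {
    cells <- dplyr::filter(cells, .data$image_id %in% images)
  }
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$cell_type)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~image_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "type") +
    ggplot2::theme_minimal()
}

#' Heatmap of prioritization summaries across source-target pairs
#'
#' @param summaries A tibble with columns `source`, `target` and one of
#'   the [sic_summary_measures()] columns.
#' @param measure Column to display (default `"strength"`); pairs are
#'   ordered by it, descending.
#' @return A ggplot tile plot.
#' @export
plot_sic_heatmap <- function(summaries, measure = "strength") {
  stopifnot(measure %in% names(summaries))
  summaries <- dplyr::arrange(summaries, dplyr::desc(.data[[measure]]))
  summaries$pair <- factor(
    paste(summaries$source, "→", summaries$target),
    levels = unique(paste(summaries$source, "→", summaries$target)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$target, y = .data$source,
                               fill = .data[[measure]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("pair prioritization by %s", measure))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
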
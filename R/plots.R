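#' Plot a dated event chronology
#'
#' Events along geological time, one row per gene family: speciations at
#' their node ages, in-branch events at their branch midpoints, terminal vs
#' internal branch events distinguished by transparency.
#'
#' @param events A [date_events()] tibble (one or more families).
#' @param periods A period table used for background shading.
#' @return A ggplot object.
#' @export
plot_event_chronology <- function(events, periods = default_periods()) {
  validate_period_table(periods)
  shading <- dplyr::mutate(periods,
                           fill = rep(c("grey95", "white"), length.out = nrow(periods)))
  ggplot2::ggplot(events) +
    ggplot2::geom_rect(
      data = shading,
      ggplot2::aes(xmin = .data$younger_Ga, xmax = .data$older_Ga,
                   ymin = -Inf, ymax = Inf),
      fill = shading$fill, colour = NA
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$date_Ga, y = .data$family,
                   shape = .data$event, colour = .data$event,
                   alpha = .data$branch_class),
      size = 3
    ) +
    ggplot2::scale_alpha_manual(values = c(internal = 1, terminal = 0.4)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ga)", y = NULL, alpha = "Branch",
                  colour = "Event", shape = "Event") +
    ggplot2::theme_minimal()
}

#' Plot an abundance-vs-phosphate fit
#'
#' Scatter of the raw data with the fitted regression curve (straight line
#' for the linear form, exponential curve for the log-linear form).
#'
#' @param fit An `abundance_fit`.
#' @param table The abundance tibble the fit was computed from.
#' @return A ggplot object.
#' @export
plot_abundance_fit <- function(fit, table) {
  stopifnot(inherits(fit, "abundance_fit"))
  xs <- seq(min(table$phosphate_uM), max(table$phosphate_uM), length.out = 200)
  curve <- tibble(phosphate_uM = xs, fitted = predict_abundance(fit, xs))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$phosphate_uM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[fit$gene]]), alpha = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted),
                       colour = "red") +
    ggplot2::labs(
      x = expression("Phosphate (" * mu * "M)"),
      y = paste(fit$gene, "relative abundance"),
      subtitle = sprintf("%s fit: slope %.3g, p = %.2g (df = %d)",
                         fit$form, fit$slope, fit$p_value, fit$df)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.abundance_fit <- function(object, table, ...) {
  plot_abundance_fit(object, table)
}
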
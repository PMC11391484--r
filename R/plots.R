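#' Plot a Lorenz curve
#'
#' Draws the cumulative resource share against the cumulative weight share
#' with the equality diagonal for reference; the gap between the two is the
#' visual counterpart of the Gini coefficient.
#'
#' @param object A `lorenz` object from [lorenz()] or [panel_lorenz()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot lorenz
autoplot.lorenz <- function(object, ...) {
  lab <- if (is.na(object$weighting)) "weight" else object$weighting
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 1, colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = paste0("Cumulative share of ", lab),
      y = "Cumulative share of personnel",
      title = sprintf("Lorenz curve (G = %.3f)", object$gini)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Gini series
#'
#' Line plot of weighted Gini coefficients over years, one line per
#' category, faceted by weighting, with the conventional 0.4 warning line.
#'
#' @param gini_series A tibble as returned by [panel_gini()].
#' @return A ggplot object.
#' @export
plot_gini_series <- function(gini_series) {
  ggplot2::ggplot(gini_series,
                  ggplot2::aes(x = .data$year, y = .data$gini,
                               colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0.4, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~weighting) +
    ggplot2::labs(x = "Year", y = "Gini coefficient", colour = "Category") +
    ggplot2::theme_minimal()
}
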
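#' Plot colour loci in the bee colour hexagon
#'
#' Diagnostic scatter of species loci inside the unit hexagon, coloured by
#' hue sector, with the achromatic centre at the origin.
#'
#' @param loci Loci tibble from [spectra_to_loci()] (columns `species`, `x`,
#'   `y`, optionally `sector`).
#' @return A ggplot object.
#' @export
plot_hexagon <- function(loci) {
  theta <- seq(0, 300, by = 60) * pi / 180
  hex <- tibble(x = sin(theta), y = cos(theta))
  hex <- bind_rows(hex, hex[1, ])
  p <- ggplot2::ggplot(loci, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = hex, colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "hexagon x", y = "hexagon y") +
    ggplot2::theme_minimal()
  if ("sector" %in% names(loci)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$sector), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Scree plot of an eigenshape decomposition
#'
#' @param object An `"eigenshape"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eigenshape
#' @export
autoplot.eigenshape <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis,
                                  y = .data$variance_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::labs(x = "eigenshape axis", y = "variance fraction",
                  title = "Eigenshape scree") +
    ggplot2::theme_minimal()
}

#' Histogram of CVA discriminant scores around the classification cutpoint
#'
#' @param object A `"cva_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cva_fit
#' @export
autoplot.cva_fit <- function(object, ...) {
  d <- tibble(score = object$scores,
              above = object$scores > object$cutpoint)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$above)) +
    ggplot2::geom_histogram(bins = 20, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = 2) +
    ggplot2::labs(x = "canonical variate score", y = "count",
                  title = "Two-group CVA discriminant scores") +
    ggplot2::theme_minimal()
}
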
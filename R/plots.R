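#' Plot a 2D localization density map
#'
#' @param object A [density_map_2d()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map_2d <- function(object, ...) {
  df <- tibble::tibble(
    a = rep(object$a_breaks[-1] - 5, times = ncol(object$values)),
    rho = rep(object$rho_breaks[-1] - 5, each = nrow(object$values)),
    value = as.vector(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$rho,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "axial position a (nm, SPB to nucleolus)",
                  y = expression(rho ~ "(nm)"),
                  title = paste("Localization density:", object$chain)) +
    ggplot2::theme_minimal()
}

#' Plot a contact map
#'
#' @param object A [contact_map()] result.
#' @param trans Transformation for the fill scale (e.g. `"log10"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, trans = "identity", ...) {
  v <- object$values
  df <- tibble::tibble(
    i = rep(seq_len(nrow(v)), times = ncol(v)),
    j = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$mode, transform = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}

#' Plot shell occupancy along the genome
#'
#' Percentage peripheral per bead, faceted by chain.
#'
#' @param occupancy Output of [shell_occupancy()].
#' @return A ggplot.
#' @export
plot_shell_occupancy <- function(occupancy) {
  ggplot2::ggplot(occupancy,
                  ggplot2::aes(x = .data$start / 1000,
                               y = .data$pct_peripheral)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "% peripheral") +
    ggplot2::theme_minimal()
}

#' Plot the fold-change vs displacement trend
#'
#' LOESS fit with a 2 SE ribbon over the gene-strain scatter summarised by
#' the fitted object.
#'
#' @param trend A [position_trend()] object.
#' @param points Optional tibble of the underlying points
#'   (`delta_pct_peripheral`, `lfc`) to draw behind the fit.
#' @return A ggplot.
#' @export
plot_position_trend <- function(trend, points = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$delta_pct_peripheral, y = .data$lfc),
      alpha = 0.2, size = 0.5)
  }
  p +
    ggplot2::geom_ribbon(
      data = trend$loess,
      ggplot2::aes(x = .data$delta_pct_peripheral,
                   ymin = .data$fit - 2 * .data$se,
                   ymax = .data$fit + 2 * .data$se),
      fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(
      data = trend$loess,
      ggplot2::aes(x = .data$delta_pct_peripheral, y = .data$fit),
      color = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * "% peripheral (pp)"),
                  y = expression(log[2] ~ "fold change")) +
    ggplot2::theme_minimal()
}

#' Plot windowed r-squared comparison
#'
#' @param windows Output of [windowed_r2_comparison()].
#' @return A ggplot of the log2 r-squared ratio per window centre.
#' @export
plot_windowed_r2 <- function(windows) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$center_kb, y = .data$log2_ratio,
                               color = .data$log2_ratio > 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "grey40"),
      guide = "none") +
    ggplot2::labs(x = "distance from deleted telomere (kb)",
                  y = expression(log[2] *
                    (r[percent ~ peripheral]^2 / r[distance]^2))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
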
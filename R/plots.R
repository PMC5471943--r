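# Quick ggplot2 companions to the SVG renderers: convenient for
# interactive inspection, not byte-stable output (use render_*() for
# that).

#' @method autoplot dyncomm_set
#' @export
autoplot.dyncomm_set <- function(object, ordering = NULL, ...) {
  ordering <- ordering %||% barycenter_order(object)
  geom <- alluvial_geometry(object, ordering, 0, 0, 100, 60)
  p <- ggplot2::ggplot()
  if (!is.null(geom$links)) {
    seg <- geom$links
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xs, y = (.data$ys0 + .data$ys1) / 2,
                   xend = .data$xk, yend = (.data$yk0 + .data$yk1) / 2,
                   linewidth = .data$count, colour = .data$color),
      alpha = 0.5)
  }
  p +
    ggplot2::geom_rect(
      data = geom$blocks,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   fill = .data$color)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "timestep", y = NULL,
                  title = "Dynamic community evolution") +
    ggplot2::theme_minimal()
}

#' @method autoplot timestep_clusterings
#' @export
autoplot.timestep_clusterings <- function(object, ...) {
  ggplot2::ggplot(k_profiles(object),
                  ggplot2::aes(x = .data$t, y = factor(.data$k),
                               fill = .data$likelihood)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "timestep", y = "K", fill = "likelihood") +
    ggplot2::theme_minimal()
}

#' @method autoplot activation_series
#' @export
autoplot.activation_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t, y = .data$node,
                               fill = .data$activation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "timestep", y = "electrode") +
    ggplot2::theme_minimal()
}
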
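#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.channel_network <- function(object, ...) {
  segs <- object$segments
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$z0, xend = .data$x1,
                   yend = .data$z1, linewidth = .data$width_um),
      lineend = "round", colour = "steelblue") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_linewidth(range = c(1, 6)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", linewidth = "width (um)",
                  title = "Channel network")
}

#' @export
autoplot.saturation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$fraction)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "saturation fraction",
                  title = "ROI saturation curve")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit$data, ggplot2::aes(y = .data$fitted),
      colour = "firebrick", linetype = 2)
  }
  p
}

#' @export
autoplot.tau_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fraction), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linetype = 2) +
    ggplot2::geom_vline(xintercept = object$tau, linetype = 3) +
    ggplot2::labs(
      x = "time (s)", y = "saturation fraction",
      title = sprintf("Exponential saturation fit: tau = %.2f s (R^2 = %.3f)",
                      object$tau, object$r_squared))
}

map_df_long <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot super-resolved maps
#'
#' @param maps An `ulm_maps` object from [accumulate_maps()].
#' @return A ggplot.
#' @export
plot_velocity_map <- function(maps) {
  df <- map_df_long(maps$velocity)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  fill = "speed (mm/s)", title = "Velocity map")
}

#' @rdname plot_velocity_map
#' @export
plot_density_map <- function(maps) {
  df <- map_df_long(maps$density)
  ggplot2::ggplot(df[df$value > 0, ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  fill = "localizations", title = "Density map")
}
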
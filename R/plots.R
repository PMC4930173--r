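#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster trajectory
#'
#' Cell paths coloured by time, with the final configuration drawn as
#' points and the final polarities as segments.
#'
#' @param object A `cg_trajectory` from [run_trajectory()].
#' @param arrow_scale Length multiplier for the polarity segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_trajectory <- function(object, arrow_scale = 0.3, ...) {
  fin <- dplyr::filter(object, .data$t == max(.data$t))
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$cell, colour = .data$t),
                       alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_point(data = fin, size = 2) +
    ggplot2::geom_segment(
      data = fin,
      ggplot2::aes(xend = .data$x + arrow_scale * .data$px,
                   yend = .data$y + arrow_scale * .data$py),
      colour = "steelblue",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "time",
                  title = sprintf("N = %d cluster trajectory",
                                  attr(object, "N")))
}

#' Plot a pitchfork fit
#'
#' Branch-averaged angular-velocity magnitudes against co-attraction
#' strength with the fitted square-root curve overlaid.
#'
#' @param object A `pitchfork_fit` from [fit_pitchfork()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pitchfork_fit <- function(object, ...) {
  dat <- object$data
  curve <- tibble::tibble(
    chi = seq(min(dat$chi), max(dat$chi), length.out = 200))
  curve$omega <- predict_pitchfork(object, curve$chi)
  ggplot2::ggplot(dat, ggplot2::aes(.data$chi, .data$omega)) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "co-attraction strength chi",
      y = "|Omega| (1 / tau)",
      title = sprintf("Rotation onset: omega0 = %.3g, chi_c = %.3g",
                      object$omega0, object$chi_c))
}

#' Plot the co-attractant field around a configuration
#'
#' Filled raster of the secreted field with the cells overlaid.
#'
#' @param positions Cell positions.
#' @param ell Degradation length.
#' @param n_grid Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_coattract_field <- function(positions, ell = 5, n_grid = 80) {
  pos <- as_positions(positions)
  fld <- coattract_field_grid(pos, ell = ell, n_grid = n_grid)
  cells <- tibble::tibble(x = pos[, 1], y = pos[, 2])
  ggplot2::ggplot(fld, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$c)) +
    ggplot2::geom_point(data = cells, colour = "black", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "c(r)")
}
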
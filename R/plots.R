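#' Plot a thickness map
#'
#' Raster display of a [thickness_map()] in object-plane mm.
#'
#' @param object A [thickness_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thickness_map <- function(object, ...) {
  px <- attr(object, "pixel_mm")
  m <- unclass(object)
  d <- tibble(
    x_mm = rep(map_x(ncol(m), px), each = nrow(m)),
    y_mm = rep(map_x(nrow(m), px), times = ncol(m)),
    thickness_mm = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm,
                                  fill = .data$thickness_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "T (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a thickness profile, optionally against the ideal chord profile
#'
#' @param object A [extract_profile()] tibble.
#' @param diameters_mm,centers_mm Optional ideal fiber parameters to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thickness_profile <- function(object, diameters_mm = NULL,
                                       centers_mm = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x_mm, .data$thickness_mm)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "x (mm)", y = "projected thickness (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(diameters_mm)) {
    th <- tibble(x_mm = object$x_mm,
                 thickness_mm = fiber_theory(object$x_mm, diameters_mm,
                                             centers_mm))
    p <- p + ggplot2::geom_line(data = th, colour = "red",
                                linetype = "dashed", linewidth = 0.4)
  }
  p
}

#' Plot experiment diameter errors
#'
#' Dot plot of the signed percent apex-diameter errors per fiber for every
#' technique / averaging / distance cell of a [run_experiment()] table.
#'
#' @param object A `fiber_experiment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fiber_experiment <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$averaging, .data$dd_t_pct,
                               colour = factor(.data$fiber))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$odd_mm),
                        cols = ggplot2::vars(.data$technique)) +
    ggplot2::labs(x = "spectrum strategy", y = "apex diameter error (%)",
                  colour = "fiber") +
    ggplot2::theme_minimal()
}
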
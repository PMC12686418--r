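#' Plot a dose curve
#'
#' @param object An `ioert_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ioert_curve
#' @export
autoplot.ioert_curve <- function(object, ...) {
  lab <- switch(curve_axis(object),
                depth = "depth [mm]", inplane = "inplane position [mm]",
                crossplane = "crossplane position [mm]")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_mm,
                                       y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sigma,
                                      ymax = .data$value + .data$sigma),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = lab, y = "dose [rel.]") +
    ggplot2::theme_minimal()
}

#' Plot per-point gamma values
#' @param object An `ioert_gamma` result.
#' @param ... Unused.
#' @method autoplot ioert_gamma
#' @export
autoplot.ioert_gamma <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$position_mm,
                                            y = .data$gamma,
                                            colour = .data$pass)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2b8cbe",
                                            `FALSE` = "#e34a33")) +
    ggplot2::labs(x = "position [mm]", y = expression(gamma),
                  colour = "pass",
                  title = sprintf("pass rate %.1f%%", object$pass_rate)) +
    ggplot2::theme_minimal()
}

#' Central-slice heatmap of a dose grid
#' @param object A `dose_grid`.
#' @param plane "xz" (default, at y = 0) or "yz".
#' @param ... Unused.
#' @method autoplot dose_grid
#' @export
autoplot.dose_grid <- function(object, plane = c("xz", "yz"), ...) {
  plane <- match.arg(plane)
  if (plane == "xz") {
    iy <- which.min(abs(grid_axis(object, 2)))
    m <- object$energy[, iy, ]
    xs <- grid_axis(object, 1)
  } else {
    ix <- which.min(abs(grid_axis(object, 1)))
    m <- object$energy[ix, , ]
    xs <- grid_axis(object, 2)
  }
  df <- tibble::tibble(
    x = rep(xs, times = object$dims[3]),
    z = rep(grid_axis(object, 3), each = length(xs)),
    dose = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("%s [mm]", substr(plane, 1, 1)),
                  y = "depth [mm]", fill = "E [MeV]") +
    ggplot2::theme_minimal()
}

#' Bar chart of relative organ doses
#' @param object An `organ_dose_table`.
#' @param min_pct Hide organs below this relative dose.
#' @param ... Unused.
#' @method autoplot organ_dose_table
#' @export
autoplot.organ_dose_table <- function(object, min_pct = 0, ...) {
  df <- dplyr::filter(object, .data$relative_pct >= min_pct)
  df <- dplyr::arrange(df, .data$relative_pct)
  df$organ <- factor(df$organ, levels = df$organ)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_pct, y = .data$organ)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose relative to target [%] (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
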
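# ggplot2 helpers for the main result types.

#' Plot a recruitment profile
#'
#' Current against mean ROI intensity, optionally with the fitted
#' two-segment line and detected inflection of a [detect_inflection()]
#' object.
#'
#' @param object A [roi_profile()] tibble or [detect_inflection()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
plot_profile <- function(object, ...) {
  if (inherits(object, "mumri_inflection")) {
    prof <- object$profile
    p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$current_mA)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$mean_intensity)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue")
    if (object$significant) {
      p <- p + ggplot2::geom_vline(xintercept = object$inflection_mA,
                                   linetype = "dashed", colour = "firebrick")
    }
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$current_mA,
                                              y = .data$mean_intensity)) +
      ggplot2::geom_point() + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "stimulation current (mA)",
                    y = "mean ROI intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_profile
#' @export
autoplot.mumri_profile <- function(object, ...) plot_profile(object, ...)

#' @rdname plot_profile
#' @export
autoplot.mumri_inflection <- function(object, ...) plot_profile(object, ...)

#' Plot a difference map
#'
#' Raster view of a (normalised) motor-unit difference map, optionally with
#' the thresholded territory outline.
#'
#' @param map Numeric matrix (difference or normalised map).
#' @param territory Optional logical matrix overlaid as tiles.
#' @param voxel_size_mm In-plane voxel size, used for physical axes.
#' @return A ggplot.
#' @export
plot_difference_map <- function(map, territory = NULL,
                                voxel_size_mm = c(1.5, 1.5)) {
  df <- tidyr::expand_grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$value <- map[cbind(df$row, df$col)]
  df$x <- (df$col - 0.5) * voxel_size_mm[2]
  df$y <- (df$row - 0.5) * voxel_size_mm[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal\ndifference") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(territory)) {
    tf <- df[territory[cbind(df$row, df$col)], ]
    p <- p + ggplot2::geom_tile(data = tf, fill = NA, colour = "white",
                                linewidth = 0.2)
  }
  p
}

#' Bland-Altman plot for two observers
#'
#' Scatter of paired differences against paired means with the bias and the
#' 95% limits of agreement (bias +/- coefficient of repeatability).
#'
#' @param a,b Numeric vectors, one value per unit for each observer.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(a, b) {
  d <- b - a
  m <- (a + b) / 2
  bias <- mean(d)
  cr <- 1.96 * sd(d)
  ggplot2::ggplot(tibble(mean = m, diff = d),
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = bias + c(-cr, cr),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of observers", y = "difference (obs2 - obs1)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
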
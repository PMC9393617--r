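#' Plot a point cloud projection
#'
#' Quick ggplot2 scatter of two coordinate axes, colored by the stored RGB
#' channels when present.
#'
#' @param object A [point_cloud()].
#' @param axes Character pair among `"x"`, `"y"`, `"z"`.
#' @param max_points Down-sample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.point_cloud <- function(object, axes = c("x", "z"), max_points = 50000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[withr::with_seed(0L, sample.int(nrow(df), max_points)), ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]]))
  if (has_colors(object)) {
    cols <- grDevices::rgb(df$r, df$g, df$b)
    p <- p + ggplot2::geom_point(color = cols, size = 0.3)
  } else {
    p <- p + ggplot2::geom_point(size = 0.3, alpha = 0.5)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = paste(axes[1], "(cm)"), y = paste(axes[2], "(cm)"))
}

#' Plot the layered projected-area profile of a trait record
#'
#' @param object A `shoot_traits` from [extract_traits()].
#' @param ... Unused.
#' @return A ggplot of per-layer projected area, bottom layer first.
#' @export
autoplot.shoot_traits <- function(object, ...) {
  la <- object$layer_projected_areas_cm2
  if (!nrow(la)) abort("trait record has no layer areas to plot.")
  ggplot2::ggplot(la, ggplot2::aes(x = .data$area_cm2,
                                   y = (.data$z_low_cm + .data$z_high_cm) / 2)) +
    ggplot2::geom_col(orientation = "y", fill = "forestgreen", alpha = 0.7,
                      width = (la$z_high_cm[1] - la$z_low_cm[1]) * 0.9) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "projected area (cm²)", y = "height (cm)",
                  title = sprintf("height %.1f cm, leaf area %.0f cm², compactness %.2f",
                                  object$plant_height_cm, object$leaf_area_cm2,
                                  object$compactness))
}

#' Plot a plate calibration fit
#'
#' Shows the detected boundary points in the plate plane together with the
#' fitted circumcircle.
#'
#' @param object A `plate_calibration` from [calibrate_scene()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plate_calibration <- function(object, ...) {
  bnd <- object$plate_fit$boundary
  th <- seq(0, 2 * pi, length.out = 200)
  # boundary coordinates are relative to the plane origin; re-fit center
  circ <- fit_circle(bnd)
  circle_df <- tibble(u = circ$center[1] + object$plate_fit$radius * cos(th),
                      v = circ$center[2] + object$plate_fit$radius * sin(th))
  ggplot2::ggplot(tibble(u = bnd[, 1], v = bnd[, 2]), ggplot2::aes(.data$u, .data$v)) +
    ggplot2::geom_path(data = circle_df, color = "red") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "u (raw units)", y = "v (raw units)",
                  title = sprintf("raw radius %.4g, scale factor %.4g",
                                  object$plate_fit$radius, object$scale_factor))
}
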
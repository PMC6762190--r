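#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted sagittal profile
#'
#' Marker points with the fitted polynomial curve, sagittal view (axial
#' coordinate horizontal, antero-posterior vertical).
#'
#' @param object A `spine_polyfit`.
#' @param n_curve Number of curve evaluation points (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spine_polyfit
#' @export
autoplot.spine_polyfit <- function(object, n_curve = 200, ...) {
  grid <- seq(object$domain[1], object$domain[2], length.out = n_curve)
  curve <- tibble(x_mm = grid, y_mm = predict(object, grid))
  pts <- as_tibble(object$source)
  ggplot(pts, aes(x = .data$x_mm, y = .data$y_mm)) +
    geom_line(data = curve, colour = "grey40") +
    geom_point() +
    labs(x = "axial position (mm, caudal → cephalic)",
         y = "antero-posterior position (mm)",
         title = sprintf("%s / %s: order-%d fit, RMSE %.2f mm",
                         object$subject_id, object$modality,
                         object$order, object$fit_rmse))
}

#' Plot a curvature series
#'
#' @param object A `curvature_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curvature_series
#' @export
autoplot.curvature_series <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$x_mm, y = .data$k_per_mm, shape = .data$endpoint)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "axial position (mm)", y = expression(k ~ (mm^-1)),
         shape = "one-sided\nendpoint")
}

#' Plot a pair of profiles in a shared sagittal frame
#'
#' Overlays two marker profiles (points and connecting lines), the standard
#' view for judging whether two modalities trace the same sagittal contour
#' at a consistent offset.
#'
#' @param a,b `marker_profile` objects.
#' @return A ggplot object.
#' @export
plot_profile_pair <- function(a, b) {
  tab <- dplyr::bind_rows(as_tibble(as_marker_profile(a)),
                          as_tibble(as_marker_profile(b)))
  ggplot(tab, aes(x = .data$x_mm, y = .data$y_mm, colour = .data$modality)) +
    geom_line(alpha = 0.5) +
    geom_point() +
    labs(x = "axial position (mm, caudal → cephalic)",
         y = "antero-posterior position (mm)")
}
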
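#' Analytic curvature of a fitted profile
#'
#' Curvature of the plane parametric curve traced by the profile,
#' \deqn{k = \frac{\|y'x'' - y''x'\|}{(x'^2 + y'^2)^{3/2}},}
#' evaluated with the explicit parametrization (x, y(x)), for which x' = 1
#' and x'' = 0, so \eqn{k = |y''| / (1 + y'^2)^{3/2}}. Derivatives are taken
#' analytically from the fitted polynomial, with the chain rule through the
#' conditioning map. Curvature measures the deviation of the profile from a
#' straight line: a line has k = 0 everywhere, a circle of radius r has
#' k = 1/r.
#'
#' By default the magnitude is returned; with `signed = TRUE` the sign of
#' \eqn{y'x'' - y''x'} is retained (for the explicit parametrization,
#' \eqn{-y''}), so that thoracic kyphosis and lumbar lordosis carry opposite
#' signs and a change in curvature direction between two profiles is visible.
#'
#' @param fit A `spine_polyfit`.
#' @param x Axial positions (mm) at which to evaluate; must lie within the
#'   fitted domain.
#' @param signed Keep the curvature sign (default `FALSE`).
#' @return A tibble of class `curvature_series` with columns `x_mm`,
#'   `k_per_mm`, `method` (`"analytic"`), `endpoint` (always `FALSE` here).
#' @export
#' @examples
#' spine <- generate_spine(spine_shape_params(), subject_id = "s1")
#' fit <- fit_profile(spine)
#' kk <- curvature_analytic(fit, seq(fit$domain[1], fit$domain[2], by = 5))
#' head(kk)
curvature_analytic <- function(fit, x, signed = FALSE) {
  stopifnot(inherits(fit, "spine_polyfit"))
  x <- as.numeric(x)
  if (any(!in_domain(fit, x))) {
    stop_spineprofile("Curvature requested outside the fitted domain.",
                      "extrapolation_error")
  }
  d <- polyfit_derivatives(fit, x)
  k <- -d$ypp / (1 + d$yp^2)^1.5    # sign of y'x'' - y''x' with x' = 1
  if (!signed) k <- abs(k)
  new_curvature_series(x, k, method = "analytic",
                       endpoint = rep(FALSE, length(x)), signed = signed)
}

#' Discrete curvature of an ordered point sequence
#'
#' Curvature at each point from the circle circumscribing the point and its
#' two neighbours (the parametric-curve formula applied to the local
#' osculating circle): for a triple with chord lengths a, b, c and signed
#' doubled triangle area `cross`, \eqn{|k| = 2|cross|/(abc)}. This is exact
#' for points on a circle, robust to uneven marker spacing, and invariant
#' under rigid motions of the point set. Endpoints reuse the first/last
#' triple (one-sided estimate) and are flagged `endpoint = TRUE` as
#' low-confidence.
#'
#' The sign convention (with `signed = TRUE`) matches
#' [curvature_analytic()]: the sign of \eqn{y'x'' - y''x'} along the
#' traversal order, so the signed value flips if the sequence is reversed.
#' Pass points ordered by increasing axial coordinate for consistency with
#' the analytic series.
#'
#' @param points A data frame with columns `x_mm`, `y_mm` (e.g. a
#'   `marker_profile`), or a two-column matrix, in traversal order.
#' @param signed Keep the curvature sign (default `FALSE`).
#' @return A tibble of class `curvature_series` with columns `x_mm`,
#'   `k_per_mm`, `method` (`"discrete"`), `endpoint`.
#' @export
curvature_discrete <- function(points, signed = FALSE) {
  if (is.matrix(points)) {
    points <- tibble(x_mm = points[, 1], y_mm = points[, 2])
  }
  x <- as.numeric(points$x_mm)
  y <- as.numeric(points$y_mm)
  n <- length(x)
  if (n < 3L) {
    stop_spineprofile("Discrete curvature needs at least 3 points.",
                      "insufficient_data_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_spineprofile("Non-finite coordinates.", "validation_error")
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) {
    stop_spineprofile("Repeated consecutive points (degenerate geometry).",
                      "degenerate_geometry_error")
  }
  triple_k <- function(i, j, l) {
    ax <- x[j] - x[i]; ay <- y[j] - y[i]
    bx <- x[l] - x[j]; by <- y[l] - y[j]
    cross <- ax * by - ay * bx                 # x'y'' - y'x'' orientation
    a <- sqrt(ax^2 + ay^2)
    b <- sqrt(bx^2 + by^2)
    cc <- sqrt((x[l] - x[i])^2 + (y[l] - y[i])^2)
    if (cc == 0) {
      stop_spineprofile("Coincident outer points in a curvature triple.",
                        "degenerate_geometry_error")
    }
    -2 * cross / (a * b * cc)                  # sign of y'x'' - y''x'
  }
  idx <- seq_len(n)
  k <- vapply(idx, function(i) {
    j <- min(max(i, 2L), n - 1L)               # interior node of the triple
    triple_k(j - 1L, j, j + 1L)
  }, numeric(1))
  if (!signed) k <- abs(k)
  endpoint <- idx %in% c(1L, n)
  new_curvature_series(x, k, method = "discrete", endpoint = endpoint,
                       signed = signed)
}

new_curvature_series <- function(x, k, method, endpoint, signed) {
  out <- tibble(x_mm = x, k_per_mm = k, method = method, endpoint = endpoint)
  attr(out, "signed") <- signed
  class(out) <- c("curvature_series", class(tibble()))
  out
}

#' Write a curvature series to CSV
#'
#' Columns `x_mm`, `k_per_mm`, `method`, `endpoint_flag`.
#'
#' @param series A `curvature_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curvature <- function(series, path) {
  tab <- tibble(x_mm = series$x_mm, k_per_mm = series$k_per_mm,
                method = series$method, endpoint_flag = series$endpoint)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}
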
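#' Fit a polynomial sagittal profile
#'
#' Least-squares fit of the antero-posterior coordinate on the axial
#' coordinate with a polynomial of the given order (7 by default). Raw axial
#' values in millimetres are severely ill-conditioned at order 7, so the fit
#' is performed in a conditioned variable `u = (x - centre)/halfwidth`
#' affinely mapped onto \[-1, 1\]; the affine map is stored with the fit and
#' applied transparently on evaluation and differentiation.
#'
#' The fit requires at least `order + 1` points and never silently reduces
#' the order. The fitted object refuses evaluation outside its axial domain
#' by default, because high-order polynomial tails diverge immediately beyond
#' the data.
#'
#' @param profile A `marker_profile` (or data frame with `x_mm`, `y_mm`).
#' @param order Polynomial order (default 7).
#' @return An object of class `spine_polyfit`: a list with `coefficients`
#'   (ascending powers of the conditioned variable), `order`, `domain`
#'   (axial range, mm), `normalization` (`centre`, `halfwidth`), `fit_rmse`
#'   (mm), `n`, `subject_id`, `modality`, and `source` (the fitted profile).
#' @seealso [fit_rmse()], [resample_profile()], [curvature_analytic()]
#' @export
#' @examples
#' spine <- generate_spine(spine_shape_params(), subject_id = "s1")
#' fit <- fit_profile(spine)
#' glance(fit)
fit_profile <- function(profile, order = 7) {
  profile <- as_marker_profile(profile)
  check_number(order, "order", min = 1)
  order <- as.integer(order)
  n <- nrow(profile)
  if (n < order + 1L) {
    stop_spineprofile(
      sprintf("Polynomial fit of order %d needs at least %d points, got %d.",
              order, order + 1L, n),
      "insufficient_data_error")
  }
  x <- profile$x_mm
  y <- profile$y_mm
  domain <- range(x)
  centre <- mean(domain)
  halfwidth <- diff(domain) / 2
  if (halfwidth <= 0) {
    stop_spineprofile("Degenerate axial domain (x_max must exceed x_min).",
                      "validation_error")
  }
  u <- (x - centre) / halfwidth
  V <- outer(u, 0:order, `^`)
  fit <- stats::lm.fit(V, y)
  beta <- unname(fit$coefficients)
  beta[is.na(beta)] <- 0
  rmse <- sqrt(mean(fit$residuals^2))
  structure(
    list(
      coefficients = beta,
      order = order,
      domain = domain,
      normalization = c(centre = centre, halfwidth = halfwidth),
      fit_rmse = rmse,
      n = n,
      subject_id = profile$subject_id[1L],
      modality = profile$modality[1L],
      source = profile
    ),
    class = "spine_polyfit"
  )
}

#' @export
print.spine_polyfit <- function(x, ...) {
  cat(sprintf(
    "<spine_polyfit> order %d, %s/%s, domain [%.1f, %.1f] mm, fit RMSE %.3g mm\n",
    x$order, x$subject_id, x$modality, x$domain[1], x$domain[2], x$fit_rmse))
  invisible(x)
}

in_domain <- function(object, x, tol = 1e-8) {
  lo <- object$domain[1] - tol * max(1, diff(object$domain))
  hi <- object$domain[2] + tol * max(1, diff(object$domain))
  x >= lo & x <= hi
}

#' Evaluate a fitted profile
#'
#' @param object A `spine_polyfit`.
#' @param x Axial positions (mm) at which to evaluate.
#' @param allow_extrapolation Evaluate outside the fitted axial domain
#'   (intended for plotting only; off by default because order-7 tails
#'   diverge beyond the data).
#' @param ... Unused.
#' @return Numeric vector of antero-posterior values (mm).
#' @export
predict.spine_polyfit <- function(object, x, allow_extrapolation = FALSE, ...) {
  x <- as.numeric(x)
  if (!allow_extrapolation && any(!in_domain(object, x))) {
    stop_spineprofile(
      sprintf("Evaluation outside the fitted domain [%.6g, %.6g] mm refused; set allow_extrapolation = TRUE only for plotting.",
              object$domain[1], object$domain[2]),
      "extrapolation_error")
  }
  u <- (x - object$normalization[["centre"]]) / object$normalization[["halfwidth"]]
  drop(outer(u, 0:object$order, `^`) %*% object$coefficients)
}

# Derivatives of the fitted polynomial with respect to x (mm), through the
# chain rule of the conditioning map: d/dx = (1/halfwidth) d/du.
polyfit_derivatives <- function(object, x) {
  u <- (x - object$normalization[["centre"]]) / object$normalization[["halfwidth"]]
  h <- object$normalization[["halfwidth"]]
  b <- object$coefficients
  d1 <- (b * (seq_along(b) - 1L))[-1L]                 # p'(u)
  d2 <- if (length(d1) > 1L) (d1 * (seq_along(d1) - 1L))[-1L] else numeric(0)
  yp_u <- drop(outer(u, seq_along(d1) - 1L, `^`) %*% d1)
  ypp_u <- if (length(d2)) drop(outer(u, seq_along(d2) - 1L, `^`) %*% d2)
           else rep(0, length(u))
  list(yp = yp_u / h, ypp = ypp_u / h^2)
}

#' Root-mean-squared error of a profile against a fitted polynomial
#'
#' Computes `sqrt(mean((y_i - poly(x_i))^2))` over the profile's points.
#' Every point must lie inside the fitted axial domain.
#'
#' @param profile A `marker_profile`.
#' @param fit A `spine_polyfit`.
#' @return RMSE in mm.
#' @export
fit_rmse <- function(profile, fit) {
  profile <- as_marker_profile(profile)
  stopifnot(inherits(fit, "spine_polyfit"))
  resid <- profile$y_mm - predict(fit, profile$x_mm)
  sqrt(mean(resid^2))
}

#' Resample a fitted profile at regular axial intervals
#'
#' Evaluates the fitted polynomial on the grid `x_start, x_start + spacing,
#' ...`, stopping at the cephalic end of the fitted domain or after `n_max`
#' points, whichever comes first. `x_start` defaults to the caudal end of the
#' fitted domain; when two profiles are compared, anchor both on the caudal
#' end of their domain overlap (see [shared_grid()]) so the grids coincide.
#'
#' @param fit A `spine_polyfit`.
#' @param spacing Grid spacing in mm (default 10).
#' @param x_start First grid position (mm); defaults to the caudal domain end.
#' @param n_max Maximum number of grid points (default unlimited).
#' @return A tibble of class `resampled_profile` with columns `x_mm`, `y_mm`
#'   and attributes `spacing` and `n_points`.
#' @export
resample_profile <- function(fit, spacing = 10, x_start = NULL, n_max = Inf) {
  stopifnot(inherits(fit, "spine_polyfit"))
  check_number(spacing, "spacing", strict_min = 0)
  if (is.null(x_start)) x_start <- fit$domain[1]
  check_number(x_start, "x_start")
  if (!in_domain(fit, x_start)) {
    stop_spineprofile("x_start must lie within the fitted domain.",
                      "extrapolation_error")
  }
  eps <- 1e-8 * max(1, diff(fit$domain))
  n_fit <- floor((fit$domain[2] - x_start + eps) / spacing) + 1
  n <- min(n_fit, n_max)
  if (n < 2) {
    stop_spineprofile(
      "Resampling grid would have fewer than 2 points (domain too short).",
      "domain_too_short_error")
  }
  grid <- x_start + spacing * (seq_len(n) - 1)
  out <- tibble(x_mm = grid, y_mm = predict(fit, grid))
  attr(out, "spacing") <- spacing
  attr(out, "n_points") <- as.integer(n)
  class(out) <- c("resampled_profile", class(tibble()))
  out
}

#' Shared resampling grid for a pair of fitted profiles
#'
#' Anchors the grid at the caudal end of the overlap of the two axial
#' domains, so that both modalities are sampled at identical positions.
#'
#' @param fit_a,fit_b `spine_polyfit` objects.
#' @param spacing Grid spacing in mm.
#' @param n_max Maximum number of grid points (default 22).
#' @return List with `x_start` and `n` to pass to [resample_profile()].
#' @export
shared_grid <- function(fit_a, fit_b, spacing = 10, n_max = 22) {
  lo <- max(fit_a$domain[1], fit_b$domain[1])
  hi <- min(fit_a$domain[2], fit_b$domain[2])
  if (hi - lo < spacing) {
    stop_spineprofile("Profile domains barely overlap; no shared grid.",
                      "domain_too_short_error")
  }
  eps <- 1e-8 * max(1, hi - lo)
  n <- min(floor((hi - lo + eps) / spacing) + 1, n_max)
  list(x_start = lo, n = as.integer(n))
}

#' Serialize and restore a fitted profile
#'
#' Writes the conditioned-space coefficients, axial domain, conditioning map
#' and fit RMSE as JSON at 17 significant digits, so that a written fit
#' restores bit-exactly.
#'
#' @param fit A `spine_polyfit`.
#' @param path JSON output path.
#' @return `write_polyfit()` returns `path` invisibly; `read_polyfit()`
#'   returns a `spine_polyfit` (without the source profile).
#' @export
write_polyfit <- function(fit, path) {
  stopifnot(inherits(fit, "spine_polyfit"))
  payload <- list(
    coefficients = fit$coefficients,
    order = fit$order,
    domain = fit$domain,
    normalization = as.list(fit$normalization),
    fit_rmse = fit$fit_rmse,
    n = fit$n,
    subject_id = fit$subject_id,
    modality = fit$modality
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_polyfit
#' @export
read_polyfit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = as.numeric(payload$coefficients),
      order = as.integer(payload$order),
      domain = as.numeric(payload$domain),
      normalization = c(centre = payload$normalization$centre,
                        halfwidth = payload$normalization$halfwidth),
      fit_rmse = payload$fit_rmse,
      n = payload$n,
      subject_id = payload$subject_id,
      modality = payload$modality,
      source = NULL
    ),
    class = "spine_polyfit"
  )
}
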
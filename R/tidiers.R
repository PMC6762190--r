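#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted spinal profile
#'
#' `tidy()` returns one row per polynomial coefficient (in the conditioned
#' variable, ascending powers); `glance()` returns a one-row fit summary;
#' `augment()` returns the source points with fitted values and residuals.
#'
#' @param x A `spine_polyfit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spine_polyfit
#' @export
tidy.spine_polyfit <- function(x, ...) {
  tibble(term = paste0("u^", seq_along(x$coefficients) - 1L),
         estimate = x$coefficients)
}

#' @rdname tidy.spine_polyfit
#' @method glance spine_polyfit
#' @export
glance.spine_polyfit <- function(x, ...) {
  tibble(subject_id = x$subject_id, modality = x$modality,
         order = x$order, n = x$n, fit_rmse = x$fit_rmse,
         domain_min = x$domain[1], domain_max = x$domain[2])
}

#' @rdname tidy.spine_polyfit
#' @method augment spine_polyfit
#' @export
augment.spine_polyfit <- function(x, ...) {
  if (is.null(x$source)) {
    stop_spineprofile("This fit carries no source profile (read from JSON?).",
                      "validation_error")
  }
  out <- as_tibble(x$source)
  out$.fitted <- predict(x, out$x_mm)
  out$.resid <- out$y_mm - out$.fitted
  out
}

#' Tidy a rigid transform
#'
#' @param x A `rigid_transform2d`.
#' @param ... Unused.
#' @return A one-row tibble with `mode`, `rotation_deg`, `dx_mm`, `dy_mm`.
#' @method tidy rigid_transform2d
#' @export
tidy.rigid_transform2d <- function(x, ...) {
  tibble(mode = x$mode, rotation_deg = x$rotation_angle * 180 / pi,
         dx_mm = x$translation[1], dy_mm = x$translation[2])
}
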
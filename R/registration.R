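#' Construct a 2D rigid transform
#'
#' A rotation (about the origin) followed by a translation, in the sagittal
#' plane. `mode` records how the transform was estimated: `"none"` (identity),
#' `"translation"` (centroid shift only, angle forced to 0), or `"rigid"`
#' (rotation + translation).
#'
#' @param rotation_angle Rotation angle in radians (counter-clockwise).
#' @param translation Length-2 numeric, (dx, dy) in mm.
#' @param mode One of `"none"`, `"translation"`, `"rigid"`.
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform <- function(rotation_angle = 0, translation = c(0, 0),
                            mode = c("rigid", "translation", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(translation), length(translation) == 2L,
            all(is.finite(translation)), is.finite(rotation_angle))
  if (mode %in% c("translation", "none") && rotation_angle != 0) {
    stop_spineprofile("rotation_angle must be 0 for translation/none modes.",
                      "validation_error")
  }
  structure(
    list(rotation_angle = rotation_angle,
         translation = as.numeric(translation),
         mode = mode),
    class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> mode %s, angle %.4f deg, translation (%.3f, %.3f) mm\n",
              x$mode, x$rotation_angle * 180 / pi,
              x$translation[1], x$translation[2]))
  invisible(x)
}

rotation_matrix <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

#' Apply a rigid transform to a marker profile
#'
#' Coordinates are rotated about the origin and then translated; level labels
#' and ordering are untouched.
#'
#' @param profile A `marker_profile`.
#' @param transform A `rigid_transform2d`.
#' @return The transformed `marker_profile`.
#' @export
apply_transform <- function(profile, transform) {
  profile <- as_marker_profile(profile)
  stopifnot(inherits(transform, "rigid_transform2d"))
  R <- rotation_matrix(transform$rotation_angle)
  xy <- cbind(profile$x_mm, profile$y_mm) %*% t(R)
  profile$x_mm <- xy[, 1] + transform$translation[1]
  profile$y_mm <- xy[, 2] + transform$translation[2]
  profile
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform2d`.
#' @return The inverse `rigid_transform2d` (same mode).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  R <- rotation_matrix(-transform$rotation_angle)
  t_inv <- -drop(R %*% transform$translation)
  structure(
    list(rotation_angle = -transform$rotation_angle,
         translation = t_inv, mode = transform$mode),
    class = "rigid_transform2d")
}

#' Register one marker profile onto another
#'
#' Estimates the rigid motion taking `source` into the coordinate frame of
#' `reference` from the level-matched marker pairs (matching is by anatomical
#' level label only, never nearest-neighbour), and returns both the transform
#' and the transformed source profile. The default estimator is the 2D
#' orthogonal Procrustes solution without scaling — both modalities are
#' metrically calibrated, so scale is never fitted — and reflections are
#' excluded by construction. `mode = "translation"` uses the centroid
#' difference only; `mode = "none"` returns the identity (useful when the
#' analysis should expose positioning differences rather than remove them).
#'
#' @param source,reference `marker_profile` objects sharing level labels
#'   (at least 2 for translation, 3 for rigid).
#' @param mode Registration mode: `"rigid"`, `"translation"`, or `"none"`.
#' @return A list with `transform` (a `rigid_transform2d`), `registered`
#'   (the transformed source profile), `shared_levels`, and `rmse` (the
#'   post-registration RMSE over the level-matched pairs, mm).
#' @export
#' @examples
#' spine <- generate_spine(spine_shape_params(), subject_id = "s1")
#' moved <- apply_transform(spine, rigid_transform(0.05, c(10, -3)))
#' reg <- register_profiles(moved, spine)
#' reg$transform
register_profiles <- function(source, reference,
                              mode = c("rigid", "translation", "none")) {
  mode <- match.arg(mode)
  source <- as_marker_profile(source)
  reference <- as_marker_profile(reference)
  shared <- intersect(source$level, reference$level)
  needed <- if (mode == "rigid") 3L else 2L
  if (length(shared) < needed) {
    stop_spineprofile(
      sprintf("Registration mode '%s' needs >= %d shared levels; shared: %s",
              mode, needed,
              if (length(shared)) paste(shared, collapse = ", ") else "none"),
      "registration_error")
  }
  S <- as.matrix(source[match(shared, source$level), c("x_mm", "y_mm")])
  Rf <- as.matrix(reference[match(shared, reference$level), c("x_mm", "y_mm")])

  if (mode == "none") {
    transform <- rigid_transform(0, c(0, 0), mode = "none")
  } else if (mode == "translation") {
    transform <- rigid_transform(0, colMeans(Rf) - colMeans(S),
                                 mode = "translation")
  } else {
    cs <- colMeans(S); cr <- colMeans(Rf)
    A <- t(sweep(Rf, 2, cr)) %*% sweep(S, 2, cs)  # cross-covariance
    sv <- svd(A)
    d <- sign(det(sv$u %*% t(sv$v)))              # exclude reflections
    Rm <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    angle <- atan2(Rm[2, 1], Rm[1, 1])
    trans <- cr - drop(Rm %*% cs)
    transform <- rigid_transform(angle, trans, mode = "rigid")
  }
  registered <- apply_transform(source, transform)
  Sreg <- as.matrix(registered[match(shared, registered$level),
                               c("x_mm", "y_mm")])
  rmse <- sqrt(mean(rowSums((Sreg - Rf)^2)))
  list(transform = transform, registered = registered,
       shared_levels = shared, rmse = rmse)
}

#' Serialize and restore a rigid transform
#'
#' JSON with fields `mode`, `rotation_deg`, `dx_mm`, `dy_mm`.
#'
#' @param transform A `rigid_transform2d`.
#' @param path JSON path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns a `rigid_transform2d`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  jsonlite::write_json(
    list(mode = transform$mode,
         rotation_deg = transform$rotation_angle * 180 / pi,
         dx_mm = transform$translation[1],
         dy_mm = transform$translation[2]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(p$rotation_deg * pi / 180, c(p$dx_mm, p$dy_mm),
                  mode = p$mode)
}
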
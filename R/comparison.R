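#' Inter-profile offset statistics
#'
#' For every anatomical level shared by the two profiles, the distance
#' between the level-matched marker pair is computed; `mu` is the mean of
#' those distances and `sigma` their standard deviation (n - 1 denominator).
#' A small `sigma` relative to `mu` indicates the two profiles run at a
#' consistent linear offset from one another (as a skin/adipose tissue layer
#' produces), while an inflated `sigma` flags levels where the offset breaks
#' down (e.g. over the gluteal soft tissue, or with a thick adipose layer).
#'
#' The default distance is the Euclidean distance between the paired markers;
#' `distance = "anteroposterior"` uses the absolute antero-posterior (y)
#' difference instead, as a sensitivity variant.
#'
#' @param a,b `marker_profile` objects sharing at least 2 level labels.
#' @param distance `"euclidean"` (default) or `"anteroposterior"`.
#' @return A list with `mu` (mm), `sigma` (mm), and `per_level` (tibble with
#'   `level`, `distance_mm` in anatomical order).
#' @export
offset_stats <- function(a, b, distance = c("euclidean", "anteroposterior")) {
  distance <- match.arg(distance)
  a <- as_marker_profile(a)
  b <- as_marker_profile(b)
  shared <- intersect(a$level, b$level)
  if (length(shared) < 2L) {
    stop_spineprofile("Offset statistics need at least 2 shared levels.",
                      "comparison_error")
  }
  ia <- match(shared, a$level); ib <- match(shared, b$level)
  d <- if (distance == "euclidean") {
    sqrt((a$x_mm[ia] - b$x_mm[ib])^2 + (a$y_mm[ia] - b$y_mm[ib])^2)
  } else {
    abs(a$y_mm[ia] - b$y_mm[ib])
  }
  per_level <- tibble(level = shared, distance_mm = d)
  rk <- level_rank(per_level$level)
  per_level <- per_level[order(ifelse(is.na(rk), Inf, rk)), , drop = FALSE]
  list(mu = mean(d), sigma = stats::sd(d), per_level = per_level)
}

assert_shared_grid <- function(a, b, tol = 1e-9) {
  if (nrow(a) != nrow(b) || any(abs(a$x_mm - b$x_mm) > tol)) {
    stop_spineprofile(
      "Resampled profiles are not on the same axial grid; re-sample both with a shared anchor and spacing (no silent interpolation).",
      "grid_alignment_error")
  }
}

#' RMSE between two resampled profiles
#'
#' Root-mean-squared difference of the antero-posterior values over a shared
#' regular axial grid — the mean linear distance between the two profiles
#' along the axial length of the spine. The grids must be identical (same
#' anchor, spacing and count); mismatched grids are an error, never silently
#' interpolated.
#'
#' @param a,b `resampled_profile` tibbles on identical grids.
#' @return RMSE in mm.
#' @export
profile_rmse <- function(a, b) {
  assert_shared_grid(a, b)
  sqrt(mean((a$y_mm - b$y_mm)^2))
}

#' Regional (thoracic/lumbar) RMSE between resampled profiles
#'
#' Splits the shared grid at `boundary_x` (the thoracolumbar junction from
#' [split_regions()]): grid points cephalic of the boundary (larger `x_mm`)
#' are thoracic, points caudal of it lumbar, and a point exactly on the
#' boundary goes to the lumbar side (caudal-inclusive rule).
#'
#' @param a,b `resampled_profile` tibbles on identical grids.
#' @param boundary_x Axial boundary (mm), inside the grid span.
#' @return Named numeric vector `c(thoracic = ..., lumbar = ...)` in mm.
#' @export
regional_rmse <- function(a, b, boundary_x) {
  assert_shared_grid(a, b)
  check_number(boundary_x, "boundary_x")
  thoracic <- a$x_mm > boundary_x
  lumbar <- !thoracic
  if (!any(thoracic) || !any(lumbar)) {
    stop_spineprofile("A region has no grid points; boundary_x must lie inside the grid span.",
                      "region_empty_error")
  }
  sq <- (a$y_mm - b$y_mm)^2
  c(thoracic = sqrt(mean(sq[thoracic])), lumbar = sqrt(mean(sq[lumbar])))
}

#' Two-sample Kolmogorov-Smirnov comparison of resampled profiles
#'
#' Tests whether the antero-posterior values of the two resampled profiles
#' are drawn from the same distribution: D = sup |ECDF(y_a) - ECDF(y_b)|,
#' with H0 that both samples come from populations with the same
#' distribution. With `exact = NULL` (default) the p-value follows
#' [stats::ks.test()]'s standard rule — exact for small samples (n*m <
#' 10^4, which covers the 22-point grids used here), asymptotic otherwise;
#' `exact = FALSE` forces the asymptotic formula.
#'
#' @param a,b `resampled_profile` tibbles (or numeric vectors of y values),
#'   each with at least 5 points.
#' @param alpha Significance level for the rejection decision (default 0.05).
#' @param exact `NULL` (standard rule), `TRUE`, or `FALSE`.
#' @return A list with `statistic` (D), `p_value`, `reject`
#'   (`p_value < alpha`), `alpha`, and `n` (the two sample sizes).
#' @export
ks_compare <- function(a, b, alpha = 0.05, exact = NULL) {
  ya <- if (is.numeric(a)) a else a$y_mm
  yb <- if (is.numeric(b)) b else b$y_mm
  if (length(ya) < 5L || length(yb) < 5L) {
    stop_spineprofile("KS comparison needs at least 5 points per sample.",
                      "insufficient_data_error")
  }
  check_number(alpha, "alpha", strict_min = 0)
  if (alpha >= 1) stop_spineprofile("alpha must be in (0, 1).", "validation_error")
  kt <- suppressWarnings(stats::ks.test(ya, yb, exact = exact))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       reject = kt$p.value < alpha, alpha = alpha,
       n = c(length(ya), length(yb)))
}

#' Consistency flags for a profile comparison
#'
#' Raises `offset_inconsistent` when the standard deviation of the
#' inter-profile distances exceeds `sigma_threshold` (the offset between the
#' profiles is not the consistent tissue-layer distance the model assumes),
#' and `distribution_mismatch` when the KS test rejects at its significance
#' level.
#'
#' @param report A comparison report row (see [run_phase1()] /
#'   [run_phase2()]), or any list/one-row data frame with `sigma` and
#'   optionally `ks_p` and `alpha` fields.
#' @param sigma_threshold Threshold on sigma, mm (default 5).
#' @return Character vector of raised flags (possibly empty).
#' @export
classify_consistency <- function(report, sigma_threshold = 5.0) {
  check_number(sigma_threshold, "sigma_threshold", min = 0)
  sigma <- report$sigma
  flags <- character(0)
  if (length(sigma) == 1L && is.finite(sigma) && sigma > sigma_threshold) {
    flags <- c(flags, "offset_inconsistent")
  }
  ks_p <- report$ks_p
  alpha <- if (!is.null(report$alpha)) report$alpha else 0.05
  if (!is.null(ks_p) && length(ks_p) == 1L && is.finite(ks_p) && ks_p < alpha) {
    flags <- c(flags, "distribution_mismatch")
  }
  flags
}
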
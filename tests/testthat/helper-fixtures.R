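# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A marker profile from raw coordinate vectors, labelled T1.. downward.
make_profile <- function(x, y, subject_id = "s1", modality = "mri_spinous") {
  marker_profile(
    tibble::tibble(level = spinal_levels()[seq_along(x)], x_mm = x, y_mm = y),
    subject_id = subject_id, modality = modality)
}

# 17 axial positions spanning [0, 420], cephalic (T1) first, matching the
# caudal->cephalic x convention (strictly decreasing row order).
default_x <- function(n = 17, span = 420) seq(span, 0, length.out = n)

# Evaluate a polynomial given mm-space coefficients (ascending powers).
poly_eval <- function(coef, x) {
  drop(outer(x, seq_along(coef) - 1L, `^`) %*% coef)
}

# Points on a circle of radius r (ordered by angle).
circle_points <- function(r, theta, centre = c(0, 0)) {
  tibble::tibble(x_mm = centre[1] + r * cos(theta),
                 y_mm = centre[2] + r * sin(theta))
}

# Brute-force circumscribed-circle curvature of a point triple.
circumcircle_k <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2))
  cc <- sqrt(sum((p3 - p1)^2))
  cross <- (p2[1] - p1[1]) * (p3[2] - p2[2]) - (p2[2] - p1[2]) * (p3[1] - p2[1])
  2 * abs(cross) / (a * b * cc)
}

# Closed-form mean of |nu * n + eps|, eps ~ N(0, sigma^2 I_2) (Rice mean):
# the expected Euclidean distance between a point and its noisy offset copy.
rice_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  x <- -nu^2 / (2 * sigma^2)
  L <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * L
}

# Generative-truth expected offset mu for a subject: mean over levels of the
# Rice mean of the injected normal displacement (fiducial vs spinous).
expected_mu <- function(subject) {
  spine <- subject$profiles$mri_spinous
  tissue <- subject$tissue
  x_L5 <- spine$x_mm[match("L5", spine$level)]
  d <- spineprofile:::tissue_offset_mm(spine$x_mm, tissue, subject$bmi, x_L5) +
    tissue$capsule_standoff
  mean(vapply(d, rice_mean, numeric(1), sigma = tissue$marker_noise_sd))
}
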
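test_that("offset statistics recover pure translations exactly", {
  a <- make_profile(default_x(), sin(default_x() / 70) * 25)
  b <- apply_transform(a, rigid_transform(0, c(0, 13.5), mode = "translation"))
  b$modality <- "mri_fiducial"
  off <- offset_stats(a, b)
  expect_equal(off$mu, 13.5, tolerance = 1e-12)
  expect_equal(off$sigma, 0, tolerance = 1e-12)
  expect_equal(nrow(off$per_level), 17L)

  same <- offset_stats(a, a)
  expect_equal(same$mu, 0)
  expect_equal(same$sigma, 0)

  short_a <- marker_profile(tibble::tibble(level = c("T1", "T2"),
                                           x_mm = c(40, 20), y_mm = c(0, 0)))
  short_b <- marker_profile(tibble::tibble(level = c("T3", "T4"),
                                           x_mm = c(40, 20), y_mm = c(0, 0)))
  expect_error(offset_stats(short_a, short_b), class = "comparison_error")
})

test_that("offset statistics are symmetric and rigid-motion invariant", {
  withr::local_seed(81)
  a <- make_profile(default_x(), sin(default_x() / 70) * 25)
  b <- make_profile(default_x() + rnorm(17), a$y_mm + 10 + rnorm(17, sd = 2))
  ab <- offset_stats(a, b)
  ba <- offset_stats(b, a)
  expect_equal(ab$mu, ba$mu)
  expect_equal(ab$sigma, ba$sigma)

  motion <- rigid_transform(0.4, c(25, -60))
  moved <- offset_stats(apply_transform(a, motion), apply_transform(b, motion))
  expect_equal(moved$mu, ab$mu, tolerance = 1e-9)
  expect_equal(moved$sigma, ab$sigma, tolerance = 1e-9)

  # algebraic identity mu^2 + sigma^2 (n-1)/n = mean squared distance
  n <- nrow(ab$per_level)
  expect_equal(ab$mu^2 + ab$sigma^2 * (n - 1) / n,
               mean(ab$per_level$distance_mm^2), tolerance = 1e-9)
})

test_that("the antero-posterior distance variant uses |y| differences only", {
  a <- make_profile(default_x(3), c(0, 0, 0))
  b <- make_profile(default_x(3) + 3, c(4, 4, 4))
  expect_equal(offset_stats(a, b)$mu, 5)
  expect_equal(offset_stats(a, b, distance = "anteroposterior")$mu, 4)
})

test_that("profile RMSE over shared grids matches hand-computed cases", {
  fit <- fit_profile(make_profile(seq(210, 0, length.out = 17), rep(0, 17)),
                     order = 1)
  a <- resample_profile(fit, spacing = 10, x_start = 0, n_max = 22)
  b <- a
  expect_equal(profile_rmse(a, b), 0)
  b$y_mm <- a$y_mm + 5
  expect_equal(profile_rmse(a, b), 5)
  expect_equal(profile_rmse(b, a), 5)
  b$y_mm <- rep(c(3, -3), 11)
  expect_equal(profile_rmse(a, b), 3)

  shifted <- a
  shifted$x_mm <- a$x_mm + 1
  expect_error(profile_rmse(a, shifted), class = "grid_alignment_error")
})

test_that("regional RMSE splits the grid caudal-inclusively", {
  fit <- fit_profile(make_profile(seq(210, 0, length.out = 17), rep(0, 17)),
                     order = 1)
  a <- resample_profile(fit, spacing = 10, x_start = 0, n_max = 22)
  b <- a
  # thoracic residual 4, lumbar 0, boundary at 105 (not a grid point)
  b$y_mm <- ifelse(a$x_mm > 105, 4, 0)
  expect_equal(regional_rmse(a, b, 105), c(thoracic = 4, lumbar = 0))
  expect_equal(regional_rmse(a, a, 105), c(thoracic = 0, lumbar = 0))

  # a grid point exactly on the boundary counts as lumbar
  b$y_mm <- ifelse(a$x_mm >= 100, 4, 0)
  reg <- regional_rmse(a, b, 100)
  expect_equal(unname(reg["thoracic"]), 4)
  expect_gt(reg[["lumbar"]], 0)

  withr::local_seed(91)
  b$y_mm <- rnorm(22)
  boundary <- 95
  reg <- regional_rmse(a, b, boundary)
  thor <- a$x_mm > boundary
  expect_equal(unname(reg["thoracic"]), sqrt(mean(b$y_mm[thor]^2)),
               tolerance = 1e-12)
  expect_equal(unname(reg["lumbar"]), sqrt(mean(b$y_mm[!thor]^2)),
               tolerance = 1e-12)

  expect_error(regional_rmse(a, b, 300), class = "region_empty_error")
})

test_that("the KS comparison matches its contracted extreme cases", {
  y <- sin(seq_len(22))
  a <- tibble::tibble(x_mm = 0:21 * 10, y_mm = y)
  same <- ks_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$reject)

  b <- a
  b$y_mm <- y + 10  # fully separated samples
  sep <- ks_compare(a, b)
  expect_equal(sep$statistic, 1)
  expect_true(sep$reject)

  expect_error(ks_compare(a$y_mm[1:4], a$y_mm), class = "insufficient_data_error")

  # independent ECDF sup-distance oracle
  withr::local_seed(101)
  ya <- rnorm(22); yb <- rnorm(22, mean = 0.5)
  d_oracle <- max(abs(stats::ecdf(ya)(sort(c(ya, yb))) -
                        stats::ecdf(yb)(sort(c(ya, yb)))))
  expect_equal(ks_compare(ya, yb)$statistic, d_oracle, tolerance = 1e-12)
})

test_that("consistency flags follow the sigma and KS thresholds", {
  expect_identical(classify_consistency(list(sigma = 2.5, ks_p = 0.4)),
                   character(0))
  expect_identical(classify_consistency(list(sigma = 7, ks_p = 0.4)),
                   "offset_inconsistent")
  expect_identical(classify_consistency(list(sigma = 2, ks_p = 0.01)),
                   "distribution_mismatch")
  expect_identical(
    classify_consistency(list(sigma = 8, ks_p = 0.01, alpha = 0.05)),
    c("offset_inconsistent", "distribution_mismatch"))
  expect_identical(
    classify_consistency(list(sigma = 4.5, ks_p = 0.4), sigma_threshold = 4),
    "offset_inconsistent")
})
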
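test_that("straight profiles have zero curvature everywhere", {
  x <- default_x()
  fit <- fit_profile(make_profile(x, 2 * x + 1))
  ka <- curvature_analytic(fit, seq(10, 410, by = 20))
  expect_lt(max(ka$k_per_mm), 1e-12)

  kd <- curvature_discrete(tibble::tibble(x_mm = c(0, 10, 25),
                                          y_mm = c(1, 21, 51)))
  expect_equal(kd$k_per_mm, c(0, 0, 0))
})

test_that("analytic curvature matches the parabola closed form", {
  a <- 0.005
  x <- seq(-100, 100, length.out = 17)
  prof <- marker_profile(
    tibble::tibble(level = spinal_levels(), x_mm = rev(x), y_mm = rev(a * x^2)))
  fit <- fit_profile(prof)
  k0 <- curvature_analytic(fit, 0)
  expect_equal(k0$k_per_mm, 2 * a, tolerance = 1e-10)
  # off-vertex closed form |2a| / (1 + (2ax)^2)^(3/2)
  k50 <- curvature_analytic(fit, 50)
  expect_equal(k50$k_per_mm, 2 * a / (1 + (2 * a * 50)^2)^1.5,
               tolerance = 1e-9)
})

test_that("discrete curvature is exact on circles of any radius", {
  for (r in c(50, 100, 300)) {
    pts <- circle_points(r, seq(0.2, 1.4, length.out = 9))
    kd <- curvature_discrete(pts)
    expect_lt(max(abs(kd$k_per_mm[!kd$endpoint] - 1 / r)), 1e-6)
  }
  # brute-force circumscribed-circle oracle on every interior triple
  pts <- circle_points(50, c(0.1, 0.3, 0.4, 0.75, 1.1))
  kd <- curvature_discrete(pts)
  m <- as.matrix(pts)
  oracle <- vapply(2:4, function(i)
    circumcircle_k(m[i - 1, ], m[i, ], m[i + 1, ]), numeric(1))
  expect_equal(kd$k_per_mm[2:4], oracle, tolerance = 1e-12)
})

test_that("discrete and analytic curvature agree on a dense sine profile", {
  x <- seq(0, 400, by = 1)
  y <- sin(2 * pi * x / 400) * 30
  k_true <- abs(-(2 * pi / 400)^2 * y) / (1 + (2 * pi / 400 * 30 * cos(2 * pi * x / 400))^2)^1.5
  kd <- curvature_discrete(tibble::tibble(x_mm = x, y_mm = y))
  interior <- !kd$endpoint & k_true > 1e-5
  expect_lt(max(abs(kd$k_per_mm[interior] / k_true[interior] - 1)), 0.02)

  # against a high-order fit of the same curve, central 80% of the domain
  idx <- seq(1, 401, by = 8)
  prof <- marker_profile(
    tibble::tibble(level = c(spinal_levels(),
                             paste0("p", seq_len(length(idx) - 17))),
                   x_mm = rev(x[idx]), y_mm = rev(y[idx])))
  fit <- fit_profile(prof, order = 10)
  centre <- x >= 40 & x <= 360 & k_true > 1e-4
  ka <- curvature_analytic(fit, x[centre])
  expect_lt(max(abs(kd$k_per_mm[centre] / ka$k_per_mm - 1)), 0.02)
})

test_that("curvature obeys the scale law k -> k/s", {
  pts <- circle_points(50, seq(0.2, 1.2, length.out = 7))
  k1 <- curvature_discrete(pts)$k_per_mm
  k3 <- curvature_discrete(dplyr::mutate(pts, x_mm = 3 * x_mm,
                                         y_mm = 3 * y_mm))$k_per_mm
  expect_equal(k3, k1 / 3, tolerance = 1e-12)
})

test_that("discrete |k| is invariant under rigid motions", {
  withr::local_seed(51)
  x <- seq(0, 400, by = 25)
  pts <- tibble::tibble(x_mm = x, y_mm = sin(x / 60) * 20 + rnorm(length(x)))
  k0 <- curvature_discrete(pts)$k_per_mm
  for (ang in c(0.3, -1.2, 2.5)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    m <- as.matrix(pts) %*% t(R)
    moved <- tibble::tibble(x_mm = m[, 1] + 13, y_mm = m[, 2] - 40)
    expect_equal(curvature_discrete(moved)$k_per_mm, k0, tolerance = 1e-9)
  }
})

test_that("unsigned curvature is the pointwise magnitude of signed", {
  x <- seq(0, 400, by = 10)
  pts <- tibble::tibble(x_mm = x, y_mm = sin(x / 50) * 15)
  ks <- curvature_discrete(pts, signed = TRUE)
  ku <- curvature_discrete(pts)
  expect_equal(ku$k_per_mm, abs(ks$k_per_mm))
  expect_true(any(ks$k_per_mm < 0) && any(ks$k_per_mm > 0))

  prof <- make_profile(default_x(), sin(default_x() / 70) * 20)
  fit <- fit_profile(prof)
  grid <- seq(20, 400, by = 20)
  expect_equal(curvature_analytic(fit, grid)$k_per_mm,
               abs(curvature_analytic(fit, grid, signed = TRUE)$k_per_mm))
})

test_that("signed conventions agree between the analytic and discrete routes", {
  x <- seq(0, 400, by = 5)
  y <- sin(2 * pi * x / 400) * 30
  prof <- marker_profile(
    tibble::tibble(level = c(spinal_levels(),
                             paste0("p", seq_len(length(x) - 17))),
                   x_mm = rev(x), y_mm = rev(y)))
  fit <- fit_profile(prof, order = 9)
  grid <- seq(65, 335, by = 30)  # avoids the inflection at x = 200 where k = 0
  ka <- curvature_analytic(fit, grid, signed = TRUE)
  kd <- curvature_discrete(tibble::tibble(x_mm = x, y_mm = y), signed = TRUE)
  kd_at <- kd$k_per_mm[match(grid, x)]
  expect_equal(sign(ka$k_per_mm), sign(kd_at))
})

test_that("degenerate curvature inputs are rejected", {
  expect_error(curvature_discrete(tibble::tibble(x_mm = c(0, 1), y_mm = c(0, 1))),
               class = "insufficient_data_error")
  expect_error(
    curvature_discrete(tibble::tibble(x_mm = c(0, 0, 1), y_mm = c(0, 0, 1))),
    class = "degenerate_geometry_error")
  prof <- make_profile(default_x(), sin(default_x() / 70))
  expect_error(curvature_analytic(fit_profile(prof), 500),
               class = "extrapolation_error")
})

test_that("curvature series serialize to the documented CSV layout", {
  pts <- circle_points(100, seq(0.2, 1, length.out = 5))
  kd <- curvature_discrete(pts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curvature(kd, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("x_mm", "k_per_mm", "method", "endpoint_flag"))
  expect_equal(back$k_per_mm, kd$k_per_mm)
})
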
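test_that("the spine generator places 17 labelled markers on the midline", {
  spine <- generate_spine(spine_shape_params(), subject_id = "s1")
  expect_s3_class(spine, "marker_profile")
  expect_equal(nrow(spine), 17L)
  expect_equal(spine$level, spinal_levels())
  expect_equal(spine$modality[1], "mri_spinous")
  expect_true(all(diff(spine$x_mm) < 0))        # T1 cephalic, x decreasing
  expect_equal(max(spine$x_mm), 420)
  expect_equal(min(spine$x_mm), 0)
  # kyphosis posterior (positive y) in thoracic, lordosis anterior in lumbar
  expect_gt(max(spine$y_mm[startsWith(spine$level, "T")]), 0)
  expect_lt(min(spine$y_mm[startsWith(spine$level, "L")]), 0)
})

test_that("a zero-amplitude spine is straight with zero curvature", {
  flat <- generate_spine(spine_shape_params(kyphosis_amplitude = 0,
                                            lordosis_amplitude = 0))
  expect_equal(flat$y_mm, rep(0, 17))
  fit <- fit_profile(flat)
  k <- curvature_analytic(fit, seq(10, 410, by = 50))
  expect_lt(max(k$k_per_mm), 1e-9)
})

test_that("the thoracic arc's apex curvature matches the sine closed form", {
  shape <- spine_shape_params()
  cum <- c(0, cumsum(shape$level_spacings))
  Lt <- (cum[12] + cum[13]) / 2
  s <- seq(0, Lt, by = 1)
  arc <- tibble::tibble(x_mm = s,
                        y_mm = shape$kyphosis_amplitude * sin(pi * s / Lt))
  kd <- curvature_discrete(arc)
  k_apex <- kd$k_per_mm[which.min(abs(s - Lt / 2))]
  expect_equal(k_apex, shape$kyphosis_amplitude * (pi / Lt)^2,
               tolerance = 0.01)
})

test_that("noise-free fiducials sit at the exact tissue offset", {
  spine <- generate_spine(spine_shape_params(), "s1")
  tissue <- tissue_params(marker_noise_sd = 0, gluteal_bulge_amplitude = 0)
  fid <- generate_fiducials(spine, tissue, bmi = 22)
  d <- sqrt((fid$x_mm - spine$x_mm)^2 + (fid$y_mm - spine$y_mm)^2)
  expect_equal(d, rep(9.5 + 4.0, 17), tolerance = 1e-9)
  expect_equal(offset_stats(spine, fid)$sigma, 0, tolerance = 1e-9)

  # the gluteal bulge raises the L5 pair distance by its amplitude
  tissue_b <- tissue_params(marker_noise_sd = 0)
  fid_b <- generate_fiducials(spine, tissue_b, bmi = 22)
  d_b <- sqrt((fid_b$x_mm - spine$x_mm)^2 + (fid_b$y_mm - spine$y_mm)^2)
  expect_equal(d_b[spine$level == "L5"] - d_b[spine$level == "T1"],
               tissue_b$gluteal_bulge_amplitude, tolerance = 1e-6)
})

test_that("noise-free surface markers are fiducials minus the capsule stand-off", {
  spine <- generate_spine(spine_shape_params(), "s1")
  tissue <- tissue_params(marker_noise_sd = 0)
  fid <- generate_fiducials(spine, tissue, bmi = 22)
  surf <- generate_surface_markers(spine, tissue, positioning_params(),
                                   bmi = 22)
  d <- sqrt((fid$x_mm - surf$x_mm)^2 + (fid$y_mm - surf$y_mm)^2)
  expect_equal(d, rep(tissue$capsule_standoff, 17), tolerance = 1e-9)
  expect_equal(surf$modality[1], "dss_surface")
})

test_that("an injected positioning rotation is recovered by registration", {
  spine <- generate_spine(spine_shape_params(), "s1")
  tissue <- tissue_params(marker_noise_sd = 0)
  fid <- generate_fiducials(spine, tissue, bmi = 22)
  surf <- generate_surface_markers(
    spine, tissue, positioning_params(rotation_deg = 5), bmi = 22)
  reg <- register_profiles(surf, fid)
  # the 4 mm normal-direction offset between the arms is not perfectly rigid,
  # so recovery is close but not exact even without noise
  expect_equal(reg$transform$rotation_angle * 180 / pi, -5, tolerance = 0.01)
})

test_that("a lumbar flexion change degrades the lumbar region most", {
  subj <- generate_subject(
    "s1", bmi = 22, tissue = tissue_params(marker_noise_sd = 0),
    positioning = positioning_params(lumbar_flexion_delta = 10), seed = 3)
  rep2 <- run_phase2(subj, pipeline_config(registration_mode = "none"))
  expect_gt(rep2$rmse_lumbar, rep2$rmse_thoracic)
})

test_that("subjects and cohorts regenerate bit-identically from their seeds", {
  s1 <- generate_subject("S01", bmi = 23, seed = 77)
  s2 <- generate_subject("S01", bmi = 23, seed = 77)
  expect_identical(s1$profiles, s2$profiles)
  s3 <- generate_subject("S01", bmi = 23, seed = 78)
  expect_false(identical(s1$profiles$mri_fiducial, s3$profiles$mri_fiducial))

  c1 <- generate_cohort(4, master_seed = 5)
  c2 <- generate_cohort(4, master_seed = 5)
  expect_identical(c1, c2)
})

test_that("the default cohort includes the documented BMI outliers", {
  cohort <- generate_cohort(10, master_seed = 9)
  bmis <- vapply(cohort, function(s) s$bmi, numeric(1))
  expect_equal(sum(bmis == 16), 1L)
  expect_equal(sum(bmis == 28), 1L)
  expect_true(all(bmis[3:10] >= 18 & bmis[3:10] <= 25))

  no_outliers <- generate_cohort(10, cohort_config(bmi_outliers = FALSE),
                                 master_seed = 9)
  bmis2 <- vapply(no_outliers, function(s) s$bmi, numeric(1))
  expect_true(all(bmis2 >= 18 & bmis2 <= 25))
})

test_that("fit RMSEs of all three profile types stay in the published range", {
  # 0.17-1.15 mm across spinous, fiducial and surface profiles; checked as a
  # distributional property on a well-positioned cohort at default noise
  rmses <- unlist(lapply(19:23, function(ms) {
    cohort <- generate_cohort(
      10, cohort_config(mispositioned = integer(0)), master_seed = ms)
    unlist(lapply(cohort, function(s)
      vapply(s$profiles, function(p) fit_profile(p)$fit_rmse, numeric(1))))
  }))
  expect_gte(mean(rmses >= 0.17 & rmses <= 1.15), 0.9)
})

test_that("offset dispersion grows with BMI across a cohort", {
  cohort <- generate_cohort(
    60, cohort_config(bmi_outliers = FALSE, mispositioned = integer(0)),
    master_seed = 13)
  stats <- vapply(cohort, function(s) {
    off <- offset_stats(s$profiles$mri_spinous, s$profiles$mri_fiducial)
    c(s$bmi, off$sigma)
  }, numeric(2))
  ct <- suppressWarnings(
    stats::cor.test(stats[1, ], stats[2, ], method = "spearman",
                    alternative = "greater"))
  expect_lt(ct$p.value, 0.01)
})
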
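#' Synthetic spinal shape parameters
#'
#' Parameters of the half-sine sagittal midline model used by the generator:
#' a posterior-convex (kyphotic) half-sine arc over the thoracic span and an
#' anterior-convex (lordotic) half-sine arc over the lumbar span, joined at
#' the thoracolumbar junction. The half-sine model is chosen because its
#' curvature has a closed form (apex curvature `A * (pi/L)^2`), giving exact
#' oracles for the downstream curvature code. Level markers are placed at
#' cumulative inter-level spacings graded from 20 mm (T1-T2) to 32 mm
#' (L4-L5), rescaled to the total length.
#'
#' @param length_T1_L5 Axial T1-to-L5 length, mm (default 420).
#' @param kyphosis_amplitude Thoracic arc amplitude, mm (default 25).
#' @param lordosis_amplitude Lumbar arc amplitude, mm (default 20).
#' @param level_spacings Optional vector of 16 positive inter-level gaps (mm)
#'   summing to `length_T1_L5`; defaults to the graded spacing above.
#' @return A list of class `spine_shape_params`.
#' @export
spine_shape_params <- function(length_T1_L5 = 420, kyphosis_amplitude = 25,
                               lordosis_amplitude = 20,
                               level_spacings = NULL) {
  check_number(length_T1_L5, "length_T1_L5", strict_min = 0)
  check_number(kyphosis_amplitude, "kyphosis_amplitude", min = 0)
  check_number(lordosis_amplitude, "lordosis_amplitude", min = 0)
  if (is.null(level_spacings)) {
    g <- seq(20, 32, length.out = 16)
    level_spacings <- g * length_T1_L5 / sum(g)
  }
  if (length(level_spacings) != 16L || any(level_spacings <= 0)) {
    stop_spineprofile("level_spacings must be 16 positive gaps.",
                      "validation_error")
  }
  if (abs(sum(level_spacings) - length_T1_L5) > 1e-6 * length_T1_L5) {
    stop_spineprofile("level_spacings must sum to length_T1_L5.",
                      "validation_error")
  }
  structure(list(length_T1_L5 = length_T1_L5,
                 kyphosis_amplitude = kyphosis_amplitude,
                 lordosis_amplitude = lordosis_amplitude,
                 level_spacings = as.numeric(level_spacings)),
            class = "spine_shape_params")
}

#' Synthetic soft-tissue parameters
#'
#' Parameters of the tissue layer separating the spinous processes from the
#' skin surface (and the MRI-visible capsule taped onto it). The displacement
#' applied along the local outward posterior normal at axial position x is
#'
#' `d(x) = base_offset + bmi_offset_slope * max(0, bmi - 22)
#'         + A_eff * exp(-(x - x_L5)^2 / (2 * gluteal_bulge_width^2))`
#'
#' plus `capsule_standoff` for the MRI fiducial capsules (the fixed 4 mm
#' skin-to-capsule-centre distance). The gluteal bulge emulates the thicker
#' soft tissue over the upper gluteal muscles; its effective amplitude grows
#' with BMI,
#' `A_eff = gluteal_bulge_amplitude * (1 + bulge_bmi_slope * max(0, bmi - 22)
#' + bulge_overweight_slope * max(0, bmi - 25))`, so that overweight subjects
#' lose the consistent-offset property (adipose masking of bony landmarks).
#' Each marker is additionally perturbed by isotropic Gaussian noise.
#'
#' @param base_offset Baseline tissue thickness, mm (default 9.5).
#' @param capsule_standoff Skin-to-capsule-centre distance, mm (fixed 4.0).
#' @param gluteal_bulge_amplitude Bulge amplitude at L5, mm (default 8).
#' @param gluteal_bulge_width Gaussian bulge width, mm (default 40).
#' @param bmi_offset_slope Added uniform thickness per BMI unit above 22,
#'   mm (default 0.8).
#' @param marker_noise_sd Isotropic marker noise SD, mm (default 0.7).
#' @param bulge_bmi_slope Relative bulge growth per BMI unit above 22
#'   (default 0.1).
#' @param bulge_overweight_slope Additional relative bulge growth per BMI
#'   unit above 25 (default 0.4).
#' @param noise_correlation Correlation between the fiducial and surface
#'   marker noise draws (default 0, the conservative independent choice; the
#'   capsules sit on top of the stickers, so correlated errors are plausible).
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(base_offset = 9.5, capsule_standoff = 4.0,
                          gluteal_bulge_amplitude = 8,
                          gluteal_bulge_width = 40,
                          bmi_offset_slope = 0.8, marker_noise_sd = 0.7,
                          bulge_bmi_slope = 0.1,
                          bulge_overweight_slope = 0.4,
                          noise_correlation = 0) {
  for (nm in c("base_offset", "capsule_standoff", "gluteal_bulge_amplitude",
               "gluteal_bulge_width", "bmi_offset_slope", "marker_noise_sd",
               "bulge_bmi_slope", "bulge_overweight_slope")) {
    check_number(get(nm), nm, min = 0)
  }
  if (noise_correlation < 0 || noise_correlation > 1) {
    stop_spineprofile("noise_correlation must be in [0, 1].", "validation_error")
  }
  structure(list(base_offset = base_offset,
                 capsule_standoff = capsule_standoff,
                 gluteal_bulge_amplitude = gluteal_bulge_amplitude,
                 gluteal_bulge_width = gluteal_bulge_width,
                 bmi_offset_slope = bmi_offset_slope,
                 marker_noise_sd = marker_noise_sd,
                 bulge_bmi_slope = bulge_bmi_slope,
                 bulge_overweight_slope = bulge_overweight_slope,
                 noise_correlation = noise_correlation),
            class = "tissue_params")
}

#' Synthetic between-modality positioning parameters
#'
#' The rigid motion (rotation about the profile centroid, then translation)
#' and the lumbar flexion change applied to the surface-scan arm relative to
#' the MRI arm, emulating the re-positioning of the subject between the two
#' scans.
#'
#' @param rotation_deg Rotation, degrees (default 0).
#' @param translation Length-2 (dx, dy), mm (default c(0, 0)).
#' @param lumbar_flexion_delta Change in lordosis amplitude between the two
#'   modalities, mm (default 0).
#' @return A list of class `positioning_params`.
#' @export
positioning_params <- function(rotation_deg = 0, translation = c(0, 0),
                               lumbar_flexion_delta = 0) {
  stopifnot(is.numeric(translation), length(translation) == 2L,
            all(is.finite(translation)), is.finite(rotation_deg),
            is.finite(lumbar_flexion_delta))
  structure(list(rotation_deg = rotation_deg,
                 translation = as.numeric(translation),
                 lumbar_flexion_delta = lumbar_flexion_delta),
            class = "positioning_params")
}

spine_midline <- function(s, shape) {
  cum <- c(0, cumsum(shape$level_spacings))
  L <- shape$length_T1_L5
  Lt <- (cum[12] + cum[13]) / 2          # thoracolumbar junction (T12/L1)
  Ll <- L - Lt
  ifelse(s <= Lt,
         shape$kyphosis_amplitude * sin(pi * s / Lt),
         -shape$lordosis_amplitude * sin(pi * (s - Lt) / Ll))
}

#' Generate a synthetic spinous-process profile
#'
#' Places the 17 thoracolumbar level markers (T1..L5) on the half-sine
#' sagittal midline of `shape`. The axial coordinate increases
#' caudal-to-cephalic (L5 at x = 0, T1 at x = `length_T1_L5`); the
#' antero-posterior coordinate increases posteriorly, so the thoracic
#' kyphosis is a positive bump and the lumbar lordosis a negative one. The
#' construction is deterministic; `seed` is accepted for interface symmetry
#' with the noisy generators.
#'
#' @param shape A `spine_shape_params`.
#' @param subject_id Subject identifier.
#' @param seed Unused (deterministic); kept for a uniform generator
#'   interface.
#' @return A `marker_profile` with modality `"mri_spinous"`, carrying the
#'   generative `shape` as an attribute (used by
#'   [generate_surface_markers()] to apply a lumbar flexion change).
#' @export
generate_spine <- function(shape = spine_shape_params(),
                           subject_id = "synthetic", seed = NULL) {
  stopifnot(inherits(shape, "spine_shape_params"))
  s <- c(0, cumsum(shape$level_spacings))   # caudally from T1
  x <- shape$length_T1_L5 - s               # caudal -> cephalic convention
  y <- spine_midline(s, shape)
  prof <- marker_profile(
    tibble(level = spinal_level_order, x_mm = x, y_mm = y),
    subject_id = subject_id, modality = "mri_spinous")
  attr(prof, "shape") <- shape
  prof
}

# Unit outward-posterior normals along a marker sequence, from central
# differences in row (anatomical) order; one-sided at the ends.
profile_normals <- function(profile) {
  x <- profile$x_mm; y <- profile$y_mm
  n <- length(x)
  j0 <- pmax(seq_len(n) - 1L, 1L)
  j1 <- pmin(seq_len(n) + 1L, n)
  tx <- x[j1] - x[j0]; ty <- y[j1] - y[j0]
  nrm <- sqrt(tx^2 + ty^2)
  nx <- -ty / nrm; ny <- tx / nrm
  flip <- ny < 0                            # posterior is +y
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  cbind(nx, ny)
}

tissue_offset_mm <- function(x, tissue, bmi, x_L5) {
  amp <- tissue$gluteal_bulge_amplitude *
    (1 + tissue$bulge_bmi_slope * max(0, bmi - 22) +
       tissue$bulge_overweight_slope * max(0, bmi - 25))
  tissue$base_offset +
    tissue$bmi_offset_slope * max(0, bmi - 22) +
    amp * exp(-(x - x_L5)^2 / (2 * tissue$gluteal_bulge_width^2))
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

draw_noise <- function(n, sd, seed) {
  if (sd == 0) return(matrix(0, n, 2))
  maybe_with_seed(seed, matrix(stats::rnorm(2L * n, sd = sd), n, 2))
}

#' Generate synthetic MRI fiducial markers from a spinous-process profile
#'
#' Displaces each spinous-process marker along the local outward posterior
#' normal by the tissue thickness `d(x)` (see [tissue_params()]) plus the
#' 4 mm capsule stand-off, then adds isotropic Gaussian marker noise. The
#' normal-direction displacement (rather than a pure antero-posterior shift)
#' preserves the consistent level-to-level distance on curved regions.
#'
#' @param spine A `marker_profile` from [generate_spine()].
#' @param tissue A `tissue_params`.
#' @param bmi Subject body mass index (default 22).
#' @param seed Seed for the noise draw (`NULL` uses the current RNG state).
#' @return A `marker_profile` with modality `"mri_fiducial"`.
#' @export
generate_fiducials <- function(spine, tissue = tissue_params(), bmi = 22,
                               seed = NULL) {
  spine <- as_marker_profile(spine)
  stopifnot(inherits(tissue, "tissue_params"))
  check_number(bmi, "bmi", strict_min = 0)
  x_L5 <- spine$x_mm[match("L5", spine$level)]
  if (is.na(x_L5)) x_L5 <- min(spine$x_mm)
  d <- tissue_offset_mm(spine$x_mm, tissue, bmi, x_L5) + tissue$capsule_standoff
  nrm <- profile_normals(spine)
  eps <- draw_noise(nrow(spine), tissue$marker_noise_sd, seed)
  out <- spine
  out$modality <- "mri_fiducial"
  out$x_mm <- spine$x_mm + d * nrm[, 1] + eps[, 1]
  out$y_mm <- spine$y_mm + d * nrm[, 2] + eps[, 2]
  attr(out, "shape") <- attr(spine, "shape")
  out
}

#' Generate synthetic surface-scan markers
#'
#' Builds the skin-surface marker positions seen by the 3D surface scanner:
#' the fiducial construction without the capsule stand-off, with an
#' independent noise draw, optionally with the lumbar lordosis amplitude
#' shifted by `positioning$lumbar_flexion_delta` (a genuine shape change that
#' no rigid registration can undo), and finally mapped by the rigid
#' positioning motion (rotation about the profile centroid, then
#' translation) emulating re-positioning between scanning sessions.
#'
#' @param spine A `marker_profile` from [generate_spine()] (its `shape`
#'   attribute is required when `lumbar_flexion_delta != 0`).
#' @param tissue A `tissue_params`.
#' @param positioning A `positioning_params`.
#' @param bmi Subject body mass index (default 22).
#' @param seed Seed for the noise draw.
#' @param fiducial_noise Optional n-by-2 matrix of the fiducial arm's noise
#'   draw, used when `tissue$noise_correlation > 0` to correlate the two
#'   arms' errors.
#' @return A `marker_profile` with modality `"dss_surface"`.
#' @export
generate_surface_markers <- function(spine, tissue = tissue_params(),
                                     positioning = positioning_params(),
                                     bmi = 22, seed = NULL,
                                     fiducial_noise = NULL) {
  spine <- as_marker_profile(spine)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(positioning, "positioning_params"))
  check_number(bmi, "bmi", strict_min = 0)

  base <- spine
  if (positioning$lumbar_flexion_delta != 0) {
    shape <- attr(spine, "shape")
    if (is.null(shape)) {
      stop_spineprofile(
        "lumbar_flexion_delta needs the generative shape (use a spine from generate_spine()).",
        "validation_error")
    }
    shape2 <- shape
    shape2$lordosis_amplitude <-
      max(0, shape$lordosis_amplitude + positioning$lumbar_flexion_delta)
    base <- generate_spine(shape2, subject_id = spine$subject_id[1L])
  }

  x_L5 <- base$x_mm[match("L5", base$level)]
  if (is.na(x_L5)) x_L5 <- min(base$x_mm)
  d <- tissue_offset_mm(base$x_mm, tissue, bmi, x_L5)
  nrm <- profile_normals(base)
  eps <- draw_noise(nrow(base), tissue$marker_noise_sd, seed)
  rho <- tissue$noise_correlation
  if (rho > 0 && !is.null(fiducial_noise)) {
    eps <- rho * fiducial_noise + sqrt(1 - rho^2) * eps
  }
  px <- base$x_mm + d * nrm[, 1] + eps[, 1]
  py <- base$y_mm + d * nrm[, 2] + eps[, 2]

  # rigid positioning motion: rotate about the centroid, then translate
  ang <- positioning$rotation_deg * pi / 180
  cx <- mean(px); cy <- mean(py)
  R <- rotation_matrix(ang)
  xy <- sweep(cbind(px, py), 2, c(cx, cy)) %*% t(R)
  px <- xy[, 1] + cx + positioning$translation[1]
  py <- xy[, 2] + cy + positioning$translation[2]

  out <- base
  out$modality <- "dss_surface"
  out$x_mm <- px
  out$y_mm <- py
  attr(out, "shape") <- attr(spine, "shape")
  out
}

#' Generate one synthetic subject
#'
#' Produces the three marker profiles of one synthetic subject —
#' `mri_spinous`, `mri_fiducial`, `dss_surface` — with independent,
#' reproducibly seeded noise streams derived from `seed`. The profiles
#' regenerate bit-identically from the same parameters and seed.
#'
#' @param subject_id Subject identifier.
#' @param bmi Body mass index.
#' @param shape,tissue,positioning Generator parameter objects.
#' @param seed Integer subject seed.
#' @return An object of class `synthetic_subject`: a list with the
#'   parameters, `seed`, and `profiles` (named list of the three
#'   `marker_profile`s).
#' @export
generate_subject <- function(subject_id = "S01", bmi = 22,
                             shape = spine_shape_params(),
                             tissue = tissue_params(),
                             positioning = positioning_params(),
                             seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  spine <- generate_spine(shape, subject_id = subject_id)
  fid_noise <- draw_noise(nrow(spine), tissue$marker_noise_sd, seeds[1])
  fid <- generate_fiducials(spine, tissue, bmi = bmi, seed = seeds[1])
  surf <- generate_surface_markers(spine, tissue, positioning, bmi = bmi,
                                   seed = seeds[2],
                                   fiducial_noise = fid_noise)
  structure(
    list(subject_id = subject_id, bmi = bmi, shape = shape, tissue = tissue,
         positioning = positioning, seed = seed,
         profiles = list(mri_spinous = spine, mri_fiducial = fid,
                         dss_surface = surf)),
    class = "synthetic_subject")
}

#' Cohort generator configuration
#'
#' Configures [generate_cohort()]. Defaults emulate the study cohort: ten
#' healthy adult subjects with BMI drawn uniformly from the healthy 18-25
#' range, one underweight (BMI 16) and one overweight (BMI 28) outlier, mild
#' random re-positioning between the MRI and surface-scan sessions for every
#' subject, and two clearly mis-positioned subjects (indices 6 and 8) whose
#' surface-scan arm carries a substantial rotation and lumbar flexion change.
#'
#' @param shape,tissue Generator parameter objects.
#' @param bmi_range Healthy BMI sampling range (default c(18, 25)).
#' @param bmi_outliers Include the BMI 16 and BMI 28 outliers as subjects 1
#'   and 2 (default TRUE).
#' @param outlier_bmis The two outlier BMI values (default c(16, 28)).
#' @param mispositioned Indices of mis-positioned subjects (default c(6, 8)).
#' @param mispositioned_rotation_deg Their rotations (default c(4, 6)).
#' @param mispositioned_flexion_mm Their lumbar flexion deltas
#'   (default c(15, 20)).
#' @param baseline_rotation_sd_deg SD of every subject's random positioning
#'   rotation (default 0.5).
#' @param baseline_translation_sd_mm SD of every subject's random positioning
#'   translation per axis (default 3).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(shape = spine_shape_params(),
                          tissue = tissue_params(),
                          bmi_range = c(18, 25), bmi_outliers = TRUE,
                          outlier_bmis = c(16, 28),
                          mispositioned = c(6L, 8L),
                          mispositioned_rotation_deg = c(4, 6),
                          mispositioned_flexion_mm = c(15, 20),
                          baseline_rotation_sd_deg = 0.5,
                          baseline_translation_sd_mm = 3) {
  structure(list(shape = shape, tissue = tissue, bmi_range = bmi_range,
                 bmi_outliers = bmi_outliers, outlier_bmis = outlier_bmis,
                 mispositioned = as.integer(mispositioned),
                 mispositioned_rotation_deg = mispositioned_rotation_deg,
                 mispositioned_flexion_mm = mispositioned_flexion_mm,
                 baseline_rotation_sd_deg = baseline_rotation_sd_deg,
                 baseline_translation_sd_mm = baseline_translation_sd_mm),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` synthetic subjects with per-subject seeds derived
#' deterministically from `master_seed`; the full generative truth (BMI,
#' positioning, tissue parameters, seeds) is retained on each subject so that
#' downstream estimates can be checked against it.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param config A `cohort_config`.
#' @param master_seed Integer master seed.
#' @return A list of `synthetic_subject` objects, of class
#'   `synthetic_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(3, master_seed = 42)
#' vapply(cohort, function(s) s$bmi, numeric(1))
generate_cohort <- function(n_subjects = 10, config = cohort_config(),
                            master_seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n_subjects >= 1)
  n <- as.integer(n_subjects)
  seeds <- derive_seeds(master_seed, n + 1L)
  draw_seed <- seeds[n + 1L]
  draws <- maybe_with_seed(draw_seed, {
    list(bmi = stats::runif(n, config$bmi_range[1], config$bmi_range[2]),
         rot = stats::rnorm(n, 0, config$baseline_rotation_sd_deg),
         dx = stats::rnorm(n, 0, config$baseline_translation_sd_mm),
         dy = stats::rnorm(n, 0, config$baseline_translation_sd_mm))
  })
  bmi <- draws$bmi
  if (config$bmi_outliers) {
    if (n >= 1L) bmi[1L] <- config$outlier_bmis[1]
    if (n >= 2L) bmi[2L] <- config$outlier_bmis[2]
  }
  subjects <- lapply(seq_len(n), function(i) {
    mp <- match(i, config$mispositioned)
    positioning <- if (!is.na(mp)) {
      positioning_params(
        rotation_deg = config$mispositioned_rotation_deg[mp],
        translation = c(draws$dx[i], draws$dy[i]),
        lumbar_flexion_delta = config$mispositioned_flexion_mm[mp])
    } else {
      positioning_params(rotation_deg = draws$rot[i],
                         translation = c(draws$dx[i], draws$dy[i]),
                         lumbar_flexion_delta = 0)
    }
    generate_subject(subject_id = sprintf("S%02d", i), bmi = bmi[i],
                     shape = config$shape, tissue = config$tissue,
                     positioning = positioning, seed = seeds[i])
  })
  structure(subjects, class = "synthetic_cohort")
}

#' Collect all marker rows of a cohort into one table
#'
#' @param cohort A `synthetic_cohort` (or list of `synthetic_subject`s).
#' @return A tibble with one row per (subject, modality, level).
#' @export
cohort_profiles <- function(cohort) {
  dplyr::bind_rows(lapply(cohort, function(s) {
    dplyr::bind_rows(lapply(s$profiles, as_tibble))
  }))
}
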
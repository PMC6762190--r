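---
title: "Quantifying sagittal spinal profiles from landmark coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sagittal spinal profiles from landmark coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineprofile)
```

## The problem

Non-contact structured-light surface scanning (3DSS) captures the shape of a
person's back without ionising radiation. Whether that external shape can
stand in for the internal sagittal alignment of the spine — the thoracic
kyphosis and lumbar lordosis that clinicians normally read off radiographs —
is an empirical question with two parts:

1. Do skin-surface markers placed over the spinous processes track the
   internal spinous-process positions (same image, MRI)?
2. Do surface-scan marker positions, once transposed into the MRI frame,
   reproduce the MRI-measured marker positions?

`spineprofile` implements the quantitative machinery for both comparisons:
polynomial profile models, plane-curve curvature, level-matched rigid
registration, offset and RMSE statistics with a thoracic/lumbar split, and a
resampled two-sample Kolmogorov–Smirnov (KS) comparison — plus a seeded
synthetic-cohort generator that provides ground truth for validating every
stage, since real participant scans are not distributable.

All analysis is restricted to the sagittal plane. Coordinates follow one
convention throughout: the axial coordinate `x_mm` increases
caudal-to-cephalic and the antero-posterior coordinate `y_mm` increases
posteriorly, both in millimetres. Files recorded with the opposite
antero-posterior sense can be ingested with `read_markers(flip_y = TRUE)`.

## Profile model

A *profile* is the ordered set of landmark coordinates for one subject and
modality: T1–L5 spinous-process levels (17 points), with optional extra
surface markers. `fit_profile()` fits a 7th-order polynomial to `y(x)` by
least squares. Two numerical choices matter:

* **Conditioning.** Raw axial values (hundreds of mm) raised to the 7th
  power make the Vandermonde system numerically useless, so the fit is done
  in `u = (x - centre)/halfwidth`, an affine map of the axial domain onto
  [-1, 1]. The map is stored with the fit and applied transparently on
  evaluation and differentiation; results are reported in mm.
* **No extrapolation.** A 7th-order tail diverges immediately outside the
  data, so evaluation beyond the fitted domain is an error by default; the
  `allow_extrapolation` flag exists for plotting only.

Fit quality is the RMSE between the marker points and the fitted curve, in
mm. The fit never silently reduces its order: fewer than `order + 1` points
is an error, and missing levels are allowed as long as enough points remain.
Only spinous-process-level markers enter the fitted profiles by default;
additional free-form stickers are carried through I/O but a deliberate
subset can always be passed to `fit_profile()` directly.

`resample_profile()` evaluates a fitted profile at regularly spaced axial
positions (10 mm by default, at most 22 points). When two profiles are
compared, the grid is anchored at the caudal end of the overlap of their
axial domains (`shared_grid()`), so both arms are sampled at identical
positions; comparing mismatched grids is an error, never a silent
interpolation.

## Curvature

Curvature measures the deviation of the profile from a straight line, via
the plane parametric-curve formula

$$k = \frac{\lVert y'x'' - y''x' \rVert}{(x'^2 + y'^2)^{3/2}},$$

in units of 1/mm. Two routes are provided because either the raw marker
points or the fitted polynomial can be the more faithful description:

* `curvature_analytic()` differentiates the fitted polynomial (chain rule
  through the conditioning map); with the explicit parametrization
  `(x, y(x))`, `k = |y''| / (1 + y'^2)^{3/2}`.
* `curvature_discrete()` estimates `k` at each point from the circle
  circumscribing the point and its two neighbours: `|k| = 2|cross|/(abc)`
  for chord lengths `a, b, c`. This local-triple estimator is exact for
  points on a circle, robust to the uneven level spacing of real marker
  sets, and exactly invariant under rigid motions of the point set.
  Endpoints reuse the first/last triple and are flagged as low-confidence
  (`endpoint = TRUE`); curvature estimates near the limits of a polynomial
  fit are similarly untrustworthy, and validation excludes roughly 10% of
  the domain at each end.

The default output is the unsigned magnitude. A signed variant (the sign of
`y'x'' - y''x'` along the traversal) is provided because a *direction*
change of curvature between two profiles — kyphosis where the other arm
shows lordosis — is diagnostically meaningful. The signed value flips if a
point sequence is traversed backwards, so pass points ordered by increasing
axial coordinate when comparing signed series.

## Registration

Surface-scan profiles live in the scanner's frame and must be transposed
into the MRI frame before comparison. `register_profiles()` matches markers
**by anatomical level label only** (never nearest-neighbour, which could
lock onto the wrong vertebra) and estimates a 2D rigid transform by
orthogonal Procrustes. Scale is never fitted — both modalities are
metrically calibrated, and fitting scale would silently absorb real
differences. Reflections are excluded by construction (determinant +1).

Three modes are available because the registration choice is itself an
analysis decision: `rigid` (default), `translation` (centroid shift only),
and `none`. An over-fitted registration can mask exactly the positioning
inconsistencies one may want to detect; the mode is therefore recorded in
every report, and validation of positioning sensitivity runs with
`mode = "none"`.

## Comparison statistics

For a profile pair, `offset_stats()` computes the Euclidean distance
between level-matched markers; `mu` is their mean and `sigma` their SD
(n−1). The Euclidean pair distance is the default because the markers share
anatomical identity, so the pairing is well-defined; an antero-posterior
variant is available (`distance = "anteroposterior"`) as a sensitivity
check. A soft-tissue layer of roughly constant thickness produces a large
`mu` with a small `sigma`; adipose masking (high BMI, gluteal region)
inflates `sigma`. `classify_consistency()` raises `offset_inconsistent`
when `sigma` exceeds 5 mm — a threshold placed between the 1–4 mm
dispersion of well-behaved subjects and the ~7 mm of the adipose-masked
regime — and `distribution_mismatch` when the KS test rejects.

`profile_rmse()` and `regional_rmse()` compare resampled profiles on their
shared grid; the regional split classifies grid points against the
thoracolumbar boundary (the T12/L1 axial midpoint from `split_regions()`),
with points exactly on the boundary going to the lumbar side
(caudal-inclusive rule, stated in every report).

`ks_compare()` applies the two-sample KS test to the antero-posterior
values of the resampled grids, computed after registration — the only
reading under which a distributional test of profile shape is meaningful
for positional data. The p-value follows `stats::ks.test()`'s standard
rule: exact for small samples (which covers the 22-point grids used here),
asymptotic for large ones; the `exact` argument forces either. The exact
default matters: the asymptotic two-sample formula is so conservative at
n = 22 that its empirical type-I error is about 0.02 at a nominal 0.05,
which would make per-subject rejections incomparable across sample sizes.
The type-I calibration of the default is verified by simulation in the test
suite (10,000 same-distribution replicates).

## The synthetic cohort

`generate_cohort()` draws subjects whose three marker profiles
(`mri_spinous`, `mri_fiducial`, `dss_surface`) have the statistical
structure the analysis assumes, with full generative truth retained:

* **Spine shape** — a half-sine kyphotic arc over the thoracic span and a
  half-sine lordotic arc over the lumbar span (T1–L5 length 420 mm,
  amplitudes 25 and 20 mm), 17 markers at spacings graded 20→32 mm. The
  half-sine form gives closed-form curvature oracles (apex curvature
  `A (pi/L)^2`). The two arcs are only C0 at the junction (the slope jump
  is ~0.09 at defaults); the resulting ~0.5 mm deviation of the noiseless
  midline from a 7th-order polynomial is a feature, not a bug — real spines
  are not polynomials either, and it keeps the synthetic fit RMSEs in a
  realistic sub-millimetre range.
* **Tissue layer** — fiducial markers sit at the spinous position displaced
  along the local outward posterior normal by a base thickness (9.5 mm),
  plus 0.8 mm per BMI unit above 22, plus a Gaussian gluteal bulge (8 mm
  amplitude, 40 mm width, centred at L5) whose effective amplitude grows
  with BMI (`1 + 0.1 max(0, bmi-22) + 0.4 max(0, bmi-25)`), plus the fixed
  4 mm skin-to-capsule stand-off. Normal-direction (not antero-posterior)
  displacement preserves the constant level-to-level distance on curved
  regions. The BMI coupling of the bulge is what makes an overweight
  subject's offset *dispersion* grow — a uniform extra thickness alone
  would leave `sigma` unchanged and could never reproduce adipose masking.
* **Noise** — isotropic Gaussian marker noise, SD 0.7 mm by default,
  consistent with sub-millimetre MRI voxels and micron-accurate surface
  scans, and calibrated (once, by simulation sweep) so that the cohort's
  polynomial fit RMSEs fall in the 0.17–1.15 mm range reported for real
  landmark data. Fiducial and surface noise draws are independent by
  default (`noise_correlation` is available, since in reality the capsules
  sit on top of the stickers).
* **Positioning** — the surface arm is mapped by a rigid motion (rotation
  about the profile centroid, then translation) and optionally has its
  lordosis amplitude shifted by `lumbar_flexion_delta`, a genuine shape
  change that no rigid registration can undo. The default 10-subject cohort
  gives every subject mild positioning wobble (rotation SD 0.5 degrees,
  translation SD 3 mm), includes BMI outliers at 16 and 28 (subjects 1 and
  2), and makes subjects 6 and 8 clearly mis-positioned (rotations of 4 and
  6 degrees with flexion deltas of 15 and 20 mm — magnitudes chosen so the
  injected shape change dominates noise-level RMSE after rigid
  registration, as grossly mis-positioned subjects do).

Everything is a pure function of (parameters, seed): subjects regenerate
bit-identically, per-subject seeds derive deterministically from the master
seed, and `simulate_cohort_files()` + `analyze_markers()` produce
byte-identical output files across runs.

What the generator does **not** emulate: coronal-plane or torsional
deformity, respiratory motion, level-identification mistakes (a sticker on
the wrong vertebra), spatially correlated soft-tissue error beyond the
single gluteal bulge, and scanner-specific artefacts. Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated under
the stated error model — not that surface scanning works on any particular
clinical population.

## Pipeline

`run_phase1()` compares `mri_spinous` with `mri_fiducial` in the shared MRI
frame (no registration): fit RMSEs, offset statistics, discrete curvature,
consistency flags. `run_phase2()` registers `dss_surface` onto
`mri_fiducial`, resamples both fits on the shared 10 mm grid (up to 22
points), and adds total/regional RMSE, analytic curvature and the KS
comparison. `cohort_summary()` pools phase-2 reports: mean/SD of the total
RMSE, regional means, flag counts, a pooled KS over all subjects'
concatenated resampled values (per-subject tests are always also reported),
and the fraction of subjects whose signed curvature agrees in direction on
at least 80% of interior grid points. Incomplete subjects are reported with
a status, never dropped silently, and every written report embeds the
configuration and package version.

```{r example}
cohort <- generate_cohort(10, master_seed = 1)
reports <- suppressWarnings(analyze_markers(cohort))
dplyr::select(dplyr::filter(reports, phase == "phase2"),
              subject_id, mu, sigma, rmse_total, rmse_thoracic,
              rmse_lumbar, ks_p, flags)
```

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle rather than
against itself: circle and sine closed forms for curvature (radii 50–300
mm, 1 mm-spaced sine samples), brute-force circumscribed-circle radii for
the discrete estimator, the chi-distribution noise floor
`E(RMSE) ~ sigma * sqrt((n-p)/n)` for the polynomial fit (200 replicates),
a 1-D optimisation over the angle as a second route to the Procrustes
solution (500 noisy replicates for unbiasedness), the closed-form Rice mean
of a noisy normal-direction offset for `mu` recovery (200 subjects), 10,000
same-distribution replicates for KS type-I calibration, and 750 replicates
per level for the KS power dose-response (rotations 0, 2, 3, 6 degrees;
power saturates at 1 from 3 degrees on, where a rotation already moves the
profile ends by ~11 mm). These sizes keep the full suite under a minute of
simulation while leaving Monte-Carlo margins comfortably wider than the
asserted tolerances.

## Known limitations

* Angle summaries (Cobb, kyphosis/lordosis angles) are deliberately out of
  scope; the package quantifies profiles and curvature, not clinical
  angles.
* The polynomial model is global: a single badly-placed marker perturbs the
  whole fit. The fit RMSE and per-level residuals (`augment()`) are the
  diagnostic.
* Signed curvature conventions depend on traversal direction; the package
  fixes one convention but cannot guess the orientation of arbitrary
  external files beyond the documented `flip_y` flag.
* The KS comparison uses the marginal distribution of antero-posterior
  values; two profiles with the same value distribution in different axial
  order would not be distinguished (the RMSE and curvature comparisons
  cover that axis).
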
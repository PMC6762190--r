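# spineprofile

Quantitative comparison of sagittal spinal profiles measured by different
modalities: MRI-derived spinous-process positions, MRI-visible skin-surface
fiducial capsules, and 3D structured-light surface scans (3DSS). The
question the package serves: can the externally visible back surface stand
in for the internal sagittal alignment of the thoracolumbar spine — the
kyphotic and lordotic contours clinicians otherwise measure with ionising
imaging?

It is aimed at biomechanics and medical-imaging researchers working with
landmark coordinate tables (one row per vertebral level T1–L5, axial and
antero-posterior coordinates in mm, sagittal plane).

## What it computes

For each subject's profile pair, the package provides

* **Polynomial profile models** — a 7th-order least-squares fit of the
  antero-posterior coordinate on the axial coordinate, computed in an
  affinely conditioned variable on [-1, 1], with the fit RMSE (mm) as the
  quality measure and no extrapolation beyond the fitted domain;
* **Curvature** `k = ‖y′x″ − y″x′‖ / (x′² + y′²)^{3/2}` (mm⁻¹), both
  analytically from the fitted polynomial and discretely from marker
  triples via the circumscribed-circle estimator, with an optional signed
  variant to compare curvature *direction*;
* **Registration** — 2D rigid orthogonal-Procrustes alignment of
  level-matched landmarks (no scaling, no reflections), used to transpose
  the surface-scan frame into the MRI frame;
* **Comparison statistics** — the level-matched offset mean μ and SD σ
  (tissue-layer consistency), the profile RMSE over a shared 10 mm
  resampling grid (≤ 22 points) with a thoracic/lumbar regional split, a
  two-sample Kolmogorov–Smirnov test on the resampled antero-posterior
  values, and consistency flags (`offset_inconsistent` when σ > 5 mm,
  `distribution_mismatch` when the KS test rejects);
* **A seeded synthetic-cohort generator** — half-sine kyphosis/lordosis
  midline, normal-direction soft-tissue offsets with a BMI-coupled gluteal
  bulge, a fixed 4 mm capsule stand-off, independent marker noise, and a
  rigid + lumbar-flexion positioning perturbation between the two
  "modalities" — providing ground truth for every downstream stage.

See `vignettes/spineprofile-methods.Rmd` for the model details and design
decisions.

## Worked example

```r
library(spineprofile)

spine <- generate_spine(spine_shape_params(), subject_id = "S01")
glance(fit_profile(spine))
#> # A tibble: 1 × 7
#>   subject_id modality    order     n fit_rmse domain_min domain_max
#> 1 S01        mri_spinous     7    17    0.500          0        420
```

The noiseless synthetic midline already carries a 0.50 mm fit RMSE — the
half-sine anatomy is deliberately not a polynomial.

```r
cohort  <- generate_cohort(10, master_seed = 1)   # BMI outliers 16/28; subjects 6 & 8 mis-positioned
reports <- analyze_markers(cohort)

dplyr::filter(reports, phase == "phase1") |>
  dplyr::select(subject_id, mu, sigma, flags)
#>    subject_id    mu sigma flags
#>  1 S01         14.4  2.46 ""
#>  2 S02         21.1  6.75 "offset_inconsistent"
#>  3 S03         15.1  2.69 ""
#>  ...
#> 10 S10         14.7  2.50 ""
```

Phase 1 (spinous processes vs fiducial capsules, same MRI frame): every
healthy-BMI subject shows a large mean offset (~14–15 mm: tissue layer plus
the 4 mm capsule stand-off) with small dispersion (σ ≈ 2–3 mm) — a
consistent skin/adipose layer. The BMI-28 subject S02 is the exception
(σ = 6.75 mm, flagged): its adipose layer breaks the constant-offset
property.

```r
attr(reports, "cohort_summary")$summary |> t()
#> Cohort summary (phase 2: MRI fiducial vs surface scan, registered)
#>   subjects:                    10
#>   profile RMSE mean (SD):      1.62 (2.09) mm
#>   thoracic / lumbar RMSE mean: 1.32 / 1.76 mm
#>   pooled KS D = 0.068, p = 0.686
#>   curvature direction agreement (>=80% of grid): 100% of subjects
```

Phase 2 (fiducials vs registered surface scan): the two mis-positioned
subjects dominate the RMSE ranking (S08: 6.68 mm, S06: 4.01 mm vs ≤ 1.5 mm
for the rest) because their lumbar flexion change is a genuine shape
difference that rigid registration cannot undo; the pooled KS test does not
reject (the marker populations share a distribution).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/spineprofile.R simulate --n 10 --seed 1 --out-dir sim/
Rscript inst/cli/spineprofile.R analyze  --markers sim/markers.csv --out-dir out/
Rscript inst/cli/spineprofile.R report   --markers sim/markers.csv
```

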
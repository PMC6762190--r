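Package: spineprofile
Title: Sagittal Spinal Profile Modelling and Surface-Topography Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the sagittal profile of the thoracolumbar
    spine from anatomical landmark coordinates and for comparing profiles
    measured by different modalities (MRI spinous processes, MRI skin-surface
    fiducial capsules, and 3D structured-light surface scans). Provides
    seventh-order polynomial profile fitting in a conditioned coordinate,
    analytic and discrete plane parametric-curve curvature, rigid
    level-matched Procrustes registration between modalities, inter-profile
    offset and root-mean-squared-error statistics with a thoracic/lumbar
    regional split, a resampled two-sample Kolmogorov-Smirnov comparison,
    and a seeded synthetic-cohort generator emulating spinal shape,
    soft-tissue offsets, marker noise, and between-modality positioning
    error for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
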
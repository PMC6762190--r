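#' Construct a validated marker profile
#'
#' A marker profile is the ordered set of sagittal-plane landmark coordinates
#' for one subject and one measurement modality: one row per anatomical level
#' (T1 through L5, plus optional free-form extras), with the axial
#' (cephalo-caudal) coordinate `x_mm` and the antero-posterior coordinate
#' `y_mm`, both in millimetres. The package-wide convention is that `x_mm`
#' increases caudal-to-cephalic and `y_mm` increases posteriorly; files using
#' the opposite antero-posterior sense can be ingested with
#' `read_markers(..., flip_y = TRUE)`.
#'
#' Rows are sorted into anatomical order (T1 cephalic first); free-form extra
#' levels are interleaved by their axial coordinate. The axial coordinate must
#' be strictly monotone along that order, levels must be unique, coordinates
#' finite, and at least two points present.
#'
#' @param data Data frame with columns `level`, `x_mm`, `y_mm` and optionally
#'   `subject_id`, `modality`.
#' @param subject_id Subject identifier; overrides any column.
#' @param modality One of `"mri_spinous"`, `"mri_fiducial"`, `"dss_surface"`;
#'   overrides any column.
#' @return A tibble of class `marker_profile` with columns `subject_id`,
#'   `modality`, `level`, `x_mm`, `y_mm`, one row per level in anatomical
#'   order.
#' @export
#' @examples
#' marker_profile(
#'   data.frame(level = c("T1", "T2", "T3"), x_mm = c(420, 400, 378),
#'              y_mm = c(0, 5, 9)),
#'   subject_id = "s1", modality = "mri_spinous"
#' )
marker_profile <- function(data, subject_id = NULL, modality = NULL) {
  data <- as_tibble(data)
  required <- c("level", "x_mm", "y_mm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_spineprofile(
      paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      "format_error")
  }
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(data)) unique(data$subject_id) else "subject"
  }
  if (is.null(modality)) {
    modality <- if ("modality" %in% names(data)) unique(data$modality) else "mri_spinous"
  }
  if (length(subject_id) != 1L || length(modality) != 1L) {
    stop_spineprofile("A marker profile holds exactly one subject and one modality.",
                      "validation_error")
  }
  modality <- match.arg(modality, c("mri_spinous", "mri_fiducial", "dss_surface"))

  out <- tibble(
    subject_id = as.character(subject_id),
    modality = modality,
    level = as.character(data$level),
    x_mm = as.numeric(data$x_mm),
    y_mm = as.numeric(data$y_mm)
  )
  validate_marker_rows(out)
  out <- order_levels(out)
  assert_monotone_x(out)
  class(out) <- c("marker_profile", class(tibble()))
  out
}

validate_marker_rows <- function(out) {
  if (nrow(out) < 2L) {
    stop_spineprofile("A marker profile needs at least 2 points.",
                      "validation_error")
  }
  bad <- !is.finite(out$x_mm) | !is.finite(out$y_mm)
  if (any(bad)) {
    stop_spineprofile(
      paste0("Non-finite coordinates at level(s): ",
             paste(out$level[bad], collapse = ", ")),
      "validation_error")
  }
  dup <- duplicated(out$level)
  if (any(dup)) {
    stop_spineprofile(
      paste0("Duplicated level(s): ", paste(unique(out$level[dup]), collapse = ", ")),
      "validation_error")
  }
  invisible(out)
}

# Sort known levels anatomically; place free-form extras by axial coordinate
# consistent with the direction implied by the known levels.
order_levels <- function(out) {
  rk <- level_rank(out$level)
  known <- out[!is.na(rk), , drop = FALSE]
  extra <- out[is.na(rk), , drop = FALSE]
  known <- known[order(rk[!is.na(rk)]), , drop = FALSE]
  if (nrow(extra) == 0L) return(known)
  if (nrow(known) < 2L) {
    stop_spineprofile("At least two thoracolumbar levels are required to orient extras.",
                      "validation_error")
  }
  decreasing <- known$x_mm[1L] > known$x_mm[nrow(known)]
  merged <- dplyr::bind_rows(known, extra)
  merged[order(merged$x_mm, decreasing = decreasing), , drop = FALSE]
}

assert_monotone_x <- function(out) {
  d <- diff(out$x_mm)
  if (!(all(d > 0) || all(d < 0))) {
    stop_spineprofile(
      "Axial coordinate x_mm must be strictly monotone along the level order.",
      "validation_error")
  }
  invisible(out)
}

#' Test or coerce marker-profile objects
#'
#' `as_marker_profile()` validates a plain data frame (for instance one
#' filtered out of a larger marker table) and returns it as a
#' `marker_profile`.
#'
#' @param x Data frame with marker-profile columns.
#' @return `as_marker_profile()` returns a validated `marker_profile` tibble;
#'   `is_marker_profile()` returns a logical.
#' @export
as_marker_profile <- function(x) {
  if (inherits(x, "marker_profile")) return(x)
  marker_profile(x)
}

#' @rdname as_marker_profile
#' @export
is_marker_profile <- function(x) inherits(x, "marker_profile")

#' Read a marker coordinate file
#'
#' Reads the plain-text marker table used throughout the package: UTF-8 CSV
#' with columns `subject_id`, `modality`, `level`, `x_mm`, `y_mm` (names
#' configurable through `schema`), `#` comment lines ignored. Rows with
#' non-finite coordinates are dropped with a warning naming the reason; a
#' duplicated (subject, modality, level) triple is an error.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping the canonical column names to
#'   the names used in the file, e.g.
#'   `c(subject_id = "id", modality = "scan", level = "lvl", x_mm = "x", y_mm = "y")`.
#' @param flip_y If `TRUE`, negate `y_mm` on input (for files whose
#'   antero-posterior axis increases anteriorly).
#' @return A list of `marker_profile` objects, one per (subject, modality)
#'   pair present in the file, levels in anatomical order. An empty file
#'   yields an empty list.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_markers_example.csv",
#'                     package = "spineprofile")
#' profiles <- read_markers(path)
#' length(profiles)  # 2 subjects x 3 modalities
read_markers <- function(path, schema = NULL, flip_y = FALSE) {
  if (!file.exists(path)) {
    stop_spineprofile(paste0("File not found: ", path), "format_error")
  }
  canonical <- c("subject_id", "modality", "level", "x_mm", "y_mm")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- schema
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop_spineprofile(
      paste0("Missing column(s) in ", path, ": ",
             paste(missing_cols, collapse = ", ")),
      "format_error")
  }
  tab <- tibble(
    subject_id = as.character(raw[[map[["subject_id"]]]]),
    modality = as.character(raw[[map[["modality"]]]]),
    level = as.character(raw[[map[["level"]]]]),
    x_mm = as.numeric(raw[[map[["x_mm"]]]]),
    y_mm = as.numeric(raw[[map[["y_mm"]]]])
  )
  if (nrow(tab) == 0L) return(list())
  if (flip_y) tab$y_mm <- -tab$y_mm

  bad <- !is.finite(tab$x_mm) | !is.finite(tab$y_mm)
  if (any(bad)) {
    warn(sprintf("Dropping %d row(s) with non-finite coordinates (rows: %s).",
                 sum(bad), paste(which(bad), collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
  }
  key <- paste(tab$subject_id, tab$modality, tab$level, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop_spineprofile(
      paste0("Duplicate (subject, modality, level) row(s): ",
             paste(gsub("\r", "/", key[dup]), collapse = "; ")),
      "validation_error")
  }

  groups <- split(tab, paste(tab$subject_id, tab$modality, sep = "\r"))
  profiles <- lapply(groups, function(g) {
    marker_profile(g, subject_id = g$subject_id[1L], modality = g$modality[1L])
  })
  unname(profiles[order(names(groups))])
}

#' Write marker profiles to a CSV file
#'
#' @param profiles A `marker_profile` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(profiles, path) {
  if (is_marker_profile(profiles)) profiles <- list(profiles)
  tab <- dplyr::bind_rows(lapply(profiles, as_tibble))
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Split a profile into thoracic and lumbar regions
#'
#' Thoracic levels are T1 through T12, lumbar levels L1 through L5. The region
#' boundary is the axial midpoint between the most caudal thoracic marker and
#' the most cephalic lumbar marker present (the T12/L1 midpoint for a complete
#' profile); it is used downstream to classify regularly resampled grid points
#' by region, with points exactly on the boundary assigned to the lumbar
#' (caudal-inclusive) side.
#'
#' @param profile A `marker_profile`.
#' @return A list with elements `thoracic` and `lumbar` (tibbles of the
#'   corresponding rows) and `boundary_x` (mm).
#' @export
split_regions <- function(profile) {
  profile <- as_marker_profile(profile)
  if (!any(profile$level %in% c("T12", "L1"))) {
    stop_spineprofile("Region split needs at least one of T12 or L1.",
                      "region_split_error")
  }
  thoracic <- profile[is_thoracic(profile$level), , drop = FALSE]
  lumbar <- profile[is_lumbar(profile$level), , drop = FALSE]
  if (nrow(thoracic) == 0L || nrow(lumbar) == 0L) {
    stop_spineprofile(
      "Region split needs markers on both sides of the thoracolumbar junction.",
      "region_split_error")
  }
  # most caudal thoracic / most cephalic lumbar by anatomical rank
  t_low <- thoracic[which.max(level_rank(thoracic$level)), ]
  l_high <- lumbar[which.min(level_rank(lumbar$level)), ]
  boundary_x <- (t_low$x_mm + l_high$x_mm) / 2
  list(thoracic = thoracic, lumbar = lumbar, boundary_x = boundary_x)
}
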
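#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical thoracolumbar level vocabulary, cephalic to caudal.
spinal_level_order <- c(paste0("T", 1:12), paste0("L", 1:5))

#' Thoracolumbar vertebral levels
#'
#' Returns the canonical cephalic-to-caudal ordering of the thoracolumbar
#' spinous-process levels, T1 through L5.
#'
#' @return Character vector of 17 level labels.
#' @export
#' @examples
#' spinal_levels()
spinal_levels <- function() spinal_level_order

is_thoracic <- function(level) level %in% paste0("T", 1:12)
is_lumbar <- function(level) level %in% paste0("L", 1:5)

# Rank of a level for anatomical sorting; free-form extras get NA.
level_rank <- function(level) match(level, spinal_level_order)

#' Derive reproducible child seeds from a master seed
#'
#' Used to give each synthetic subject (and each noise stream within a
#' subject) an independent, reproducible RNG seed. Seeds stay below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  withr::with_seed(as.integer(master_seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

stop_spineprofile <- function(message, class) {
  abort(message, class = c(class, "spineprofile_error"))
}

check_number <- function(x, name, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_spineprofile(sprintf("`%s` must be a single finite number.", name),
                      "validation_error")
  }
  if (!is.null(strict_min) && x <= strict_min) {
    stop_spineprofile(sprintf("`%s` must be > %g.", name, strict_min),
                      "validation_error")
  }
  if (x < min) {
    stop_spineprofile(sprintf("`%s` must be >= %g.", name, min),
                      "validation_error")
  }
  invisible(x)
}
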
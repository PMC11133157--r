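#' Screen and area-of-interest geometry
#'
#' Pixel geometry of the presentation screen and the rectangular area of
#' interest (AoI) used by the gaze filter. Coordinates use the eye-tracker
#' convention: origin at the top-left corner, x rightward, y downward, px.
#'
#' The default mirrors a 27-inch 109-ppi screen viewed at 60 cm
#' (2560 x 1440 px) with a centrally presented 10 x 10 degree stimulus:
#' side = 2 * 600 * tan(5 deg) mm ~ 105 mm ~ 450 px, plus a 1 cm ~ 43 px
#' margin on each side.
#'
#' @param width,height screen size, px.
#' @param aoi_left,aoi_top,aoi_right,aoi_bottom AoI rectangle, px.
#' @return A `screen_geometry` list.
#' @export
screen_geometry <- function(width = 2560, height = 1440,
                            aoi_left = 1012, aoi_top = 452,
                            aoi_right = 1548, aoi_bottom = 988) {
  if (aoi_left >= aoi_right || aoi_top >= aoi_bottom) {
    stop_config("AoI must satisfy left < right and top < bottom")
  }
  if (aoi_left <= 0 || aoi_top <= 0 || aoi_right >= width || aoi_bottom >= height) {
    stop_config("AoI rectangle must lie strictly inside the screen")
  }
  structure(list(width = width, height = height,
                 aoi_left = aoi_left, aoi_top = aoi_top,
                 aoi_right = aoi_right, aoi_bottom = aoi_bottom),
            class = "screen_geometry")
}

sample_cols_required <- c("participant_id", "block", "trial", "t_trial",
                          "pupil_left", "pupil_right", "gaze_x", "gaze_y")
sample_cols_truth <- c("pupil_true", "is_blink", "is_trackloss", "is_extreme")

validate_sample_table <- function(tab) {
  missing_cols <- setdiff(sample_cols_required, names(tab))
  if (length(missing_cols)) {
    stop_schema(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) return(invisible(tab))
  bad_block <- setdiff(unique(tab$block), c("audiovisual", "visual"))
  if (length(bad_block)) {
    stop_schema(paste0("block must be 'audiovisual' or 'visual'; found: ",
                       paste(bad_block, collapse = ", ")))
  }
  key <- paste(tab$participant_id, tab$block, tab$trial, tab$t_trial)
  if (anyDuplicated(key)) {
    stop_integrity("duplicate (participant_id, block, trial, t_trial) key")
  }
  if (any(tab$trial < 1, na.rm = TRUE) || any(tab$t_trial < 0, na.rm = TRUE)) {
    stop_schema("trial must be >= 1 and t_trial must be >= 0")
  }
  pv <- c(tab$pupil_left, tab$pupil_right)
  if (any(pv <= 0, na.rm = TRUE)) {
    stop_schema("pupil values, when present, must be positive")
  }
  invisible(tab)
}

#' Read a long-format sample table from CSV
#'
#' Comma-delimited, decimal point, UTF-8; empty fields are missing values.
#' Validates the schema (required columns, block levels, positive pupil
#' values) and the uniqueness of the (participant, block, trial, t_trial)
#' key. `col_map` renames source columns to the expected schema, e.g.
#' `c(pupil_left = "PupilLeftMM")`.
#'
#' @param path file path.
#' @param col_map optional named character vector mapping schema names to
#'   source column names.
#' @return A validated tibble sample table.
#' @export
read_samples <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  # base R parsing: strtod is correctly rounded, so values written with a
  # shortest round-trip representation re-read to the identical double
  tab <- tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                           check.names = FALSE))
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      src <- col_map[[schema_name]]
      if (src %in% names(tab)) names(tab)[names(tab) == src] <- schema_name
    }
  }
  validate_sample_table(tab)
  tab$participant_id <- as.integer(tab$participant_id)
  tab$trial <- as.integer(tab$trial)
  tab$block <- as.character(tab$block)
  for (cc in c("is_blink", "is_trackloss", "is_extreme")) {
    if (cc %in% names(tab)) tab[[cc]] <- as.logical(tab[[cc]])
  }
  tab
}

#' Write a sample table to CSV
#'
#' One header row; missing values as empty fields; stable column order
#' (required columns first, ground-truth columns after, in schema order).
#'
#' @param table a sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  validate_sample_table(table)
  ord <- c(sample_cols_required, intersect(sample_cols_truth, names(table)),
           setdiff(names(table), c(sample_cols_required, sample_cols_truth)))
  readr::write_csv(table[ord], path, na = "")
  invisible(path)
}

#' Write multiverse result tables
#'
#' Writes the tidy specification-curve table (one row per dataset x model
#' estimate, with the fork levels, estimate, CI, significance and direction)
#' and the per-dataset model-comparison table (BICs, delta BIC, winner and
#' both R-squared values) as `<path_prefix>_estimates.csv` and
#' `<path_prefix>_comparisons.csv`.
#'
#' @param curve a spec curve from [build_spec_curve()].
#' @param comparisons comparison table from [run_multiverse()].
#' @param path_prefix file stem for the two outputs.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(curve, comparisons, path_prefix) {
  if (is.null(curve) || is.null(comparisons) ||
      !nrow(curve$points) || !nrow(comparisons)) {
    stop_state("multiverse run is empty or incomplete; nothing written")
  }
  f_est <- paste0(path_prefix, "_estimates.csv")
  f_cmp <- paste0(path_prefix, "_comparisons.csv")
  readr::write_csv(curve$points, f_est, na = "")
  readr::write_csv(comparisons, f_cmp, na = "")
  invisible(c(estimates = f_est, comparisons = f_cmp))
}
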
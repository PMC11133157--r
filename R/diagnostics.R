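#' Missingness and blink diagnostics for a recording
#'
#' Produces the standard sanity-check tables for an infant pupillometry
#' session: (a) per-sample eye-missingness pattern counts (left only, right
#' only, both) and a per-participant trackloss-over-time table (fraction of
#' binocularly missing samples per 1-s trial window); (b) per-participant
#' blink counts under each of the four pre-gap-handling lattice variants
#' (all/trimmed x whole-screen/AoI); (c) per-participant missing percentage
#' under each variant with the 30% exclusion flag.
#'
#' @param table a sample table.
#' @param geom a [screen_geometry()].
#' @param max_blink_ms blink classification threshold, ms.
#' @return A `pupil_diagnostics` list of tibbles: `eye_patterns`,
#'   `trackloss_by_time`, `blink_counts`, `missingness`.
#' @export
diagnostics <- function(table, geom = screen_geometry(), max_blink_ms = 500) {
  validate_sample_table(table)
  ln <- is.na(table$pupil_left)
  rn <- is.na(table$pupil_right)
  eye_patterns <- tibble::tibble(
    pattern = c("none_missing", "left_only", "right_only", "both_missing"),
    n = c(sum(!ln & !rn), sum(ln & !rn), sum(!ln & rn), sum(ln & rn))
  )

  trackloss_by_time <- if (nrow(table)) {
    dplyr::summarise(
      dplyr::group_by(table, participant_id, block, trial),
      missing_frac = mean(is.na(pupil_left) | is.na(pupil_right)),
      .groups = "drop"
    )
  } else {
    tibble::tibble(participant_id = integer(0), block = character(0),
                   trial = integer(0), missing_frac = numeric(0))
  }

  tab <- average_eyes(table)
  variants <- list(
    `all|screen` = function(x) x,
    `trimmed|screen` = function(x) filter_extreme(x),
    `all|aoi` = function(x) filter_aoi(x, geom),
    `trimmed|aoi` = function(x) filter_aoi(filter_extreme(x), geom)
  )
  blink_counts <- list()
  missingness <- list()
  for (v in names(variants)) {
    tv <- variants[[v]](tab)
    segs <- detect_blinks(tv, max_blink_ms)
    bc <- if (nrow(segs)) {
      dplyr::count(segs[segs$type == "blink", ], participant_id,
                   name = "n_blinks")
    } else {
      tibble::tibble(participant_id = integer(0), n_blinks = integer(0))
    }
    ids <- tibble::tibble(participant_id = sort(unique(tab$participant_id)))
    bc <- dplyr::left_join(ids, bc, by = "participant_id")
    bc$n_blinks[is.na(bc$n_blinks)] <- 0L
    bc$variant <- v
    blink_counts[[v]] <- bc
    mv <- participant_missingness(tv)
    mv$variant <- v
    missingness[[v]] <- mv
  }

  structure(list(
    eye_patterns = eye_patterns,
    trackloss_by_time = trackloss_by_time,
    blink_counts = dplyr::bind_rows(blink_counts),
    missingness = dplyr::bind_rows(missingness)
  ), class = "pupil_diagnostics")
}

#' @export
print.pupil_diagnostics <- function(x, ...) {
  cat("<pupil_diagnostics>\n")
  cat("  eye patterns:", paste(x$eye_patterns$pattern, x$eye_patterns$n,
                               sep = "=", collapse = ", "), "\n")
  flagged <- unique(x$missingness$participant_id[x$missingness$flagged])
  cat("  participants over 30% missing (any variant):",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")
  invisible(x)
}
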
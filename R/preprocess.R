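#' Average the two eyes into a monocular series
#'
#' Adds a `pupil` column: the mean of left and right pupil diameter when
#' both are present, missing when either eye is missing (the monocular case
#' is deferred to gap handling, which either drops or interpolates it).
#'
#' @param table a sample table.
#' @return The table with a `pupil` column.
#' @export
average_eyes <- function(table) {
  validate_sample_table(table)
  table$pupil <- ifelse(is.na(table$pupil_left) | is.na(table$pupil_right),
                        NA_real_, (table$pupil_left + table$pupil_right) / 2)
  table
}

#' Trim extreme-yet-plausible pupil values
#'
#' Values outside the open physiological interval (`low`, `high`) mm are set
#' missing (strict inequalities: exactly 2 mm or 8 mm is removed).
#'
#' @param series a table with a `pupil` column.
#' @param low,high bounds in mm.
#' @return The filtered table.
#' @export
filter_extreme <- function(series, low = 2, high = 8) {
  if (low >= high) stop_config("low must be < high")
  bad <- !is.na(series$pupil) & (series$pupil <= low | series$pupil >= high)
  series$pupil[bad] <- NA_real_
  attr(series, "n_extreme_removed") <- sum(bad)
  series
}

#' Keep only samples whose gaze falls inside the area of interest
#'
#' Membership uses the closed AoI rectangle (points exactly on an edge are
#' kept). Samples with missing gaze, or gaze outside the rectangle, have
#' their pupil value set missing.
#'
#' @param table a table with `pupil`, `gaze_x`, `gaze_y` columns.
#' @param geom a [screen_geometry()].
#' @return The filtered table.
#' @export
filter_aoi <- function(table, geom) {
  if (!inherits(geom, "screen_geometry")) stop_config("geom must be a screen_geometry")
  inside <- !is.na(table$gaze_x) & !is.na(table$gaze_y) &
    table$gaze_x >= geom$aoi_left & table$gaze_x <= geom$aoi_right &
    table$gaze_y >= geom$aoi_top & table$gaze_y <= geom$aoi_bottom
  bad <- !is.na(table$pupil) & !inside
  table$pupil[bad] <- NA_real_
  attr(table, "n_aoi_removed") <- sum(bad)
  table
}

block_time <- function(series, trial_duration) {
  (series$trial - 1) * trial_duration + series$t_trial
}

infer_trial_duration <- function(series) {
  ts <- sort(unique(series$t_trial))
  if (length(ts) < 2) return(1000)
  dt <- stats::median(diff(ts))
  max(ts) + dt
}

#' Detect blink segments in a monocular series
#'
#' Maximal runs of consecutive missing samples within a (participant,
#' block), on the block time line. Runs with duration between `min_blink_ms`
#' and `max_blink_ms` are classified as blinks; longer runs as trackloss;
#' shorter ones (single-sample dropouts, typically tracker noise or trimmed
#' outliers rather than eyelid closures) as dropouts.
#'
#' @param series a table with a `pupil` column.
#' @param max_blink_ms blink/trackloss classification threshold, ms.
#' @param min_blink_ms minimum physiological blink duration, ms.
#' @return A tibble of segments: participant_id, block, start, end (block
#'   time, ms), n_samples, type (`"blink"`/`"trackloss"`/`"dropout"`).
#' @export
detect_blinks <- function(series, max_blink_ms = 500, min_blink_ms = 50) {
  trial_duration <- infer_trial_duration(series)
  series <- dplyr::arrange(series, participant_id, block, trial, t_trial)
  bt <- block_time(series, trial_duration)
  ts <- sort(unique(series$t_trial))
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else trial_duration
  key <- paste(series$participant_id, series$block)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- rle(is.na(series$pupil[idx]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    miss <- which(r$values)
    for (m in miss) {
      seg <- idx[starts[m]:ends[m]]
      n <- length(seg)
      dur <- n * dt
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = series$participant_id[seg[1]],
        block = series$block[seg[1]],
        start = bt[seg[1]],
        end = bt[seg[1]] + dur,
        n_samples = n,
        type = if (dur > max_blink_ms) "trackloss"
               else if (dur >= min_blink_ms) "blink" else "dropout"
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(participant_id = integer(0), block = character(0),
                          start = numeric(0), end = numeric(0),
                          n_samples = integer(0), type = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Resolve missing samples by exclusion or linear interpolation
#'
#' `exclude` drops missing samples. `interpolate` fills interior missing
#' runs by linear interpolation between the nearest observed neighbours on
#' the block time line, within the same (participant, block); leading or
#' trailing runs with no neighbour on one side stay missing and are
#' dropped. Observed values are never altered. A (participant, block) with
#' zero observed samples is dropped with a warning.
#'
#' @param series a table with a `pupil` column.
#' @param mode `"exclude"` or `"interpolate"`.
#' @return The gap-handled table (no missing `pupil` values remain).
#' @export
handle_gaps <- function(series, mode = c("exclude", "interpolate")) {
  mode <- match.arg(mode)
  trial_duration <- infer_trial_duration(series)
  series <- dplyr::arrange(series, participant_id, block, trial, t_trial)
  n_missing <- sum(is.na(series$pupil))
  if (mode == "interpolate" && n_missing > 0) {
    bt <- block_time(series, trial_duration)
    key <- paste(series$participant_id, series$block)
    for (k in unique(key)) {
      idx <- which(key == k)
      obs <- !is.na(series$pupil[idx])
      if (!any(obs)) {
        warning("participant/block unit with zero observed samples dropped: ", k)
        next
      }
      if (all(obs) || sum(obs) < 2) next
      filled <- approx(bt[idx][obs], series$pupil[idx][obs],
                       xout = bt[idx], method = "linear", rule = 1)$y
      series$pupil[idx][!obs] <- filled[!obs]
    }
  }
  n_filled <- n_missing - sum(is.na(series$pupil))
  out <- series[!is.na(series$pupil), , drop = FALSE]
  attr(out, "n_gap_dropped") <- n_missing - n_filled
  attr(out, "n_interpolated") <- n_filled
  out
}

#' Subtractive (or divisive) baseline correction per trial
#'
#' For each (participant, block, trial) the baseline is the median of the
#' observed samples with `t_trial < window_ms`; `subtractive` yields
#' `y = pupil - baseline`, `divisive` yields `y = pupil / baseline`. Trials
#' with no observed sample in the window (or, for divisive, a non-positive
#' baseline) are dropped with a provenance count.
#'
#' @param series a gap-handled table with a `pupil` column.
#' @param window_ms baseline window: 16, 100 or 200 ms.
#' @param method `"subtractive"` (the lattice default) or `"divisive"`.
#' @return The table with a `y` column of baseline-corrected pupil change.
#' @export
baseline_correct <- function(series, window_ms = 16,
                             method = c("subtractive", "divisive")) {
  method <- match.arg(method)
  grp <- dplyr::group_by(series, participant_id, block, trial)
  out <- dplyr::mutate(
    grp,
    baseline = stats::median(pupil[t_trial < window_ms], na.rm = TRUE)
  )
  out <- dplyr::ungroup(out)
  no_base <- is.na(out$baseline)
  n_dropped <- length(unique(paste(out$participant_id, out$block,
                                   out$trial)[no_base]))
  if (method == "divisive") {
    nonpos <- !no_base & out$baseline <= 0
    if (any(nonpos)) {
      warning("trial(s) with non-positive baseline dropped in divisive correction")
      n_dropped <- n_dropped +
        length(unique(paste(out$participant_id, out$block, out$trial)[nonpos]))
      no_base <- no_base | nonpos
    }
    out$y <- out$pupil / out$baseline
  } else {
    out$y <- out$pupil - out$baseline
  }
  out <- out[!no_base, , drop = FALSE]
  out$baseline <- NULL
  attr(out, "n_trials_dropped_baseline") <- n_dropped
  out
}

#' Per-participant missingness fraction
#'
#' Measured post-filter and pre-gap-handling: the fraction of expected
#' samples (2 blocks x trials x samples per trial) whose `pupil` value is
#' missing. Participants with a fraction strictly above 0.30 are flagged.
#'
#' @param table a table with a `pupil` column, one row per expected sample.
#' @param threshold exclusion cutoff (strict inequality).
#' @return A tibble: participant_id, n_expected, n_missing, missing_frac,
#'   flagged.
#' @export
participant_missingness <- function(table, threshold = 0.30) {
  out <- dplyr::summarise(
    dplyr::group_by(table, participant_id),
    n_expected = dplyr::n(),
    n_missing = sum(is.na(pupil)),
    .groups = "drop"
  )
  out$missing_frac <- out$n_missing / out$n_expected
  out$flagged <- out$missing_frac > threshold
  out
}

new_processed_dataset <- function(fork, data, provenance, degenerate = FALSE,
                                  reason = NA_character_) {
  structure(list(fork = fork, data = data, provenance = provenance,
                 degenerate = degenerate, reason = reason),
            class = "processed_dataset")
}

#' Construct a model-ready processed dataset
#'
#' Thin constructor for a `processed_dataset` (fork provenance + rows with a
#' complete `y` column), used by [build_multiverse()] and handy for building
#' small fixtures in tests.
#'
#' @param data tibble with participant_id, block, trial, t_trial, y.
#' @param fork the [fork_spec()] that produced it (optional).
#' @param provenance named list of per-step counts.
#' @return A `processed_dataset`.
#' @export
processed_dataset <- function(data, fork = NULL, provenance = list()) {
  stopifnot(all(c("participant_id", "block", "trial", "t_trial", "y") %in%
                  names(data)))
  if (any(is.na(data$y))) stop_integrity("processed data must have no missing y")
  degen <- nrow(data) == 0 ||
    length(unique(data$participant_id)) < 2 ||
    length(unique(data$block)) < 2
  new_processed_dataset(fork, tibble::as_tibble(data), provenance,
                        degenerate = degen,
                        reason = if (degen) "too few rows/participants/blocks" else NA_character_)
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat("<processed_dataset>",
      if (!is.null(x$fork)) fork_token(x$fork) else "(no fork)",
      "-", nrow(x$data), "rows",
      if (x$degenerate) paste0("[degenerate: ", x$reason, "]") else "", "\n")
  invisible(x)
}

#' Expand a recording into the preprocessing multiverse
#'
#' Applies the forking operators in the fixed order: eye averaging ->
#' extreme-value filter -> AoI filter -> gap handling -> subtractive
#' baseline correction -> participant exclusion (missingness measured
#' post-filter, pre-gap-handling). `steps = 5` yields the full 48-dataset
#' lattice; smaller values stop the lattice after the corresponding degree
#' of freedom (steps 2, 3, 4 give 4, 8 and 24 variants) with downstream
#' operators fixed at identity, which is useful for diagnostics.
#'
#' Forks for which no fit-able data remain (no rows, fewer than two
#' participants, or a missing block level) are flagged degenerate but kept
#' in the lattice.
#'
#' @param table a sample table.
#' @param geom a [screen_geometry()].
#' @param steps how many degrees of freedom to fork over (2-5).
#' @param max_blink_ms blink classification threshold passed to diagnostics.
#' @return A list of `processed_dataset` objects (one per fork).
#' @export
build_multiverse <- function(table, geom = screen_geometry(), steps = 5,
                             max_blink_ms = 500) {
  stopifnot(steps %in% 2:5)
  tab <- average_eyes(table)
  out <- list()
  for (ef in fork_levels$extreme_filter) {
    t1 <- if (ef == "trimmed") filter_extreme(tab) else tab
    n_ext <- attr(t1, "n_extreme_removed") %||% 0L
    for (af in fork_levels$aoi_filter) {
      t2 <- if (af == "aoi_only") filter_aoi(t1, geom) else t1
      n_aoi <- attr(t2, "n_aoi_removed") %||% 0L
      miss <- participant_missingness(t2)
      if (steps == 2) {
        fork <- fork_spec(ef, af)
        prov <- list(n_input = nrow(tab), n_extreme_removed = n_ext,
                     n_aoi_removed = n_aoi)
        out[[length(out) + 1]] <- partial_dataset(fork, t2, prov, stage = 2)
        next
      }
      for (gh in fork_levels$gap_handling) {
        t3 <- handle_gaps(t2, gh)
        prov3 <- list(n_input = nrow(tab), n_extreme_removed = n_ext,
                      n_aoi_removed = n_aoi,
                      n_gap_dropped = attr(t3, "n_gap_dropped"),
                      n_interpolated = attr(t3, "n_interpolated"))
        if (steps == 3) {
          fork <- fork_spec(ef, af, gh)
          out[[length(out) + 1]] <- partial_dataset(fork, t3, prov3, stage = 3)
          next
        }
        for (bw in fork_levels$baseline_ms) {
          t4 <- baseline_correct(t3, bw, "subtractive")
          prov4 <- c(prov3, list(
            n_trials_dropped_baseline = attr(t4, "n_trials_dropped_baseline")))
          if (steps == 4) {
            fork <- fork_spec(ef, af, gh, bw)
            out[[length(out) + 1]] <- partial_dataset(fork, t4, prov4, stage = 4)
            next
          }
          for (pr in fork_levels$participant_rule) {
            fork <- fork_spec(ef, af, gh, bw, pr)
            excluded <- integer(0)
            t5 <- t4
            if (pr == "exclude_high_missing") {
              excluded <- miss$participant_id[miss$flagged]
              t5 <- t4[!t4$participant_id %in% excluded, , drop = FALSE]
            }
            prov5 <- c(prov4, list(excluded_participants = excluded,
                                   n_rows_final = nrow(t5)))
            keep <- c("participant_id", "block", "trial", "t_trial", "y")
            dat <- tibble::as_tibble(t5[intersect(keep, names(t5))])
            out[[length(out) + 1]] <-
              if (nrow(dat) == 0 ||
                  length(unique(dat$participant_id)) < 2 ||
                  length(unique(dat$block)) < 2) {
                new_processed_dataset(fork, dat, prov5, degenerate = TRUE,
                                      reason = "no fit-able data for this fork")
              } else {
                new_processed_dataset(fork, dat, prov5)
              }
          }
        }
      }
    }
  }
  out
}

# Intermediate lattice stages keep the working columns; they are not
# model-ready, only countable/inspectable.
partial_dataset <- function(fork, data, prov, stage) {
  structure(list(fork = fork, data = tibble::as_tibble(data),
                 provenance = prov, stage = stage),
            class = "partial_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
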
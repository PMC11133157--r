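#' Run the full multiverse: 48 datasets x 2 models
#'
#' Expands the recording into the 48-dataset preprocessing lattice and fits
#' both the time model and the no-time model to every non-degenerate
#' dataset. Fit errors are recorded per fork, never fatal to the run.
#'
#' @param table a sample table.
#' @param geom a [screen_geometry()].
#' @param spec_time,spec_no_time the two [model_spec()]s.
#' @param forks optional character vector of fork tokens to restrict the run.
#' @param verbose print one line per fork.
#' @return A list: `fits` (named list of per-fork lists with `time_model` /
#'   `no_time_model` entries, a `pupil_fit` or an error message), `comparisons`
#'   (48-row tibble with delta BIC, winner, evidence and both R-squared),
#'   `datasets` (the processed lattice).
#' @export
run_multiverse <- function(table, geom = screen_geometry(),
                           spec_time = model_spec("time_model"),
                           spec_no_time = model_spec("no_time_model"),
                           forks = NULL, verbose = FALSE) {
  lattice <- build_multiverse(table, geom)
  if (!is.null(forks)) {
    keep <- vapply(lattice, function(d) fork_token(d$fork) %in% forks,
                   logical(1))
    lattice <- lattice[keep]
    if (!length(lattice)) stop_config("no lattice fork matches the requested tokens")
  }
  fits <- list()
  cmp <- list()
  for (ds in lattice) {
    tok <- fork_token(ds$fork)
    one <- list(time_model = NULL, no_time_model = NULL)
    if (ds$degenerate) {
      one$time_model <- one$no_time_model <- paste0("degenerate: ", ds$reason)
    } else {
      one$time_model <- tryCatch(fit_model(ds, spec_time),
                                 error = function(e) conditionMessage(e))
      one$no_time_model <- tryCatch(fit_model(ds, spec_no_time),
                                    error = function(e) conditionMessage(e))
    }
    fits[[tok]] <- one
    ok_t <- inherits(one$time_model, "pupil_fit")
    ok_n <- inherits(one$no_time_model, "pupil_fit")
    bic_t <- if (ok_t) one$time_model$bic else NA_real_
    bic_n <- if (ok_n) one$no_time_model$bic else NA_real_
    winner <- if (ok_t && ok_n) {
      if (bic_t <= bic_n) "time_model" else "no_time_model"
    } else NA_character_
    delta <- if (ok_t && ok_n) abs(bic_t - bic_n) else NA_real_
    cmp[[tok]] <- tibble::tibble(
      fork_token = tok,
      extreme_filter = ds$fork$extreme_filter,
      aoi_filter = ds$fork$aoi_filter,
      gap_handling = ds$fork$gap_handling,
      baseline_ms = ds$fork$baseline_ms,
      participant_rule = ds$fork$participant_rule,
      n_rows = nrow(ds$data),
      degenerate = ds$degenerate,
      bic_time = bic_t,
      bic_no_time = bic_n,
      delta_bic = delta,
      winner = winner,
      evidence = if (!is.na(delta)) delta_bic_label(delta) else NA_character_,
      r2_time = if (ok_t) one$time_model$r2 else NA_real_,
      r2_no_time = if (ok_n) one$no_time_model$r2 else NA_real_
    )
    if (verbose) {
      message(sprintf("%-28s rows=%6d  %s", tok, nrow(ds$data),
                      if (is.na(winner)) "skipped" else
                        sprintf("winner=%s dBIC=%.1f", winner, delta)))
    }
  }
  list(fits = fits, comparisons = dplyr::bind_rows(cmp), datasets = lattice)
}

#' Assemble the specification curve from the multiverse fits
#'
#' One point per (dataset, model) estimate of the Visual - Audiovisual
#' block effect, sorted ascending by estimate (ties broken by fork token),
#' with its CI, significance (CI excluding zero) and direction. Failed or
#' degenerate fits are flagged absent and excluded from the summary counts.
#'
#' @param fits the `fits` element of a [run_multiverse()] result.
#' @return A `spec_curve` object: `points` tibble and summary counts.
#' @export
build_spec_curve <- function(fits) {
  if (!length(fits)) stop_state("no fits to assemble")
  rows <- list()
  for (tok in names(fits)) {
    fork <- parse_fork_token(tok)
    for (kind in c("time_model", "no_time_model")) {
      f <- fits[[tok]][[kind]]
      ok <- inherits(f, "pupil_fit")
      rows[[length(rows) + 1]] <- tibble::tibble(
        fork_token = tok,
        extreme_filter = fork$extreme_filter,
        aoi_filter = fork$aoi_filter,
        gap_handling = fork$gap_handling,
        baseline_ms = fork$baseline_ms,
        participant_rule = fork$participant_rule,
        model_kind = kind,
        absent = !ok,
        estimate = if (ok) f$beta_hat else NA_real_,
        ci_low = if (ok) f$beta_ci[1] else NA_real_,
        ci_high = if (ok) f$beta_ci[2] else NA_real_,
        significant = if (ok) (f$beta_ci[1] > 0 || f$beta_ci[2] < 0) else NA,
        direction = if (!ok) NA_character_ else if (f$beta_ci[1] > 0) {
          "positive"
        } else if (f$beta_ci[2] < 0) "negative" else "none"
      )
    }
  }
  pts <- dplyr::bind_rows(rows)
  pts <- pts[order(is.na(pts$estimate), pts$estimate, pts$fork_token,
                   pts$model_kind), , drop = FALSE]
  pts$rank <- seq_len(nrow(pts))
  present <- pts[!pts$absent, , drop = FALSE]
  structure(list(
    points = pts,
    n_points = sum(!pts$absent),
    n_positive = sum(present$direction == "positive"),
    n_negative = sum(present$direction == "negative"),
    n_nonsig = sum(present$direction == "none")
  ), class = "spec_curve")
}

#' @export
print.spec_curve <- function(x, ...) {
  cat("<spec_curve>", x$n_points, "estimates:",
      x$n_positive, "positive,", x$n_negative, "negative,",
      x$n_nonsig, "non-significant\n")
  invisible(x)
}
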
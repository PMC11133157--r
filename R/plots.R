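#' Plot the specification curve with its fork matrix
#'
#' Upper panel: the sorted block-effect estimates with CIs, coloured by
#' significance and direction (blue positive, red negative, grey
#' non-significant). Lower panel: the fork levels behind each estimate.
#' Panels are stacked with patchwork when available; otherwise the estimate
#' panel alone is returned.
#'
#' @param curve a [build_spec_curve()] result.
#' @return A ggplot (or patchwork) object.
#' @export
plot_spec_curve <- function(curve) {
  stopifnot(inherits(curve, "spec_curve"))
  pts <- curve$points[!curve$points$absent, , drop = FALSE]
  cols <- c(positive = "#2166ac", negative = "#b2182b", none = "grey60")
  p1 <- ggplot2::ggplot(pts, ggplot2::aes(x = rank, y = estimate,
                                          colour = direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                            alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::labs(x = NULL, y = "Visual - Audiovisual (mm)") +
    ggplot2::theme_minimal()
  long <- tidyr::pivot_longer(
    dplyr::mutate(pts, baseline_ms = as.character(baseline_ms)),
    c("extreme_filter", "aoi_filter", "gap_handling", "baseline_ms",
      "participant_rule", "model_kind"),
    names_to = "fork", values_to = "level")
  p2 <- ggplot2::ggplot(long, ggplot2::aes(x = rank, y = level,
                                           colour = direction)) +
    ggplot2::geom_point(shape = 124, size = 2) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::facet_grid(fork ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "specification (sorted by estimate)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(1, 1.6))
  } else {
    p1
  }
}

#' Plot delta BIC and R-squared across the lattice
#'
#' One panel for the BIC difference between the no-time and time models
#' (positive favours the time model) and one for the two adjusted
#' R-squared values, split by fork levels.
#'
#' @param comparisons the `comparisons` tibble of [run_multiverse()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(comparisons) {
  cmp <- comparisons[!comparisons$degenerate & !is.na(comparisons$delta_bic), ,
                     drop = FALSE]
  long <- dplyr::bind_rows(
    tibble::tibble(fork_token = cmp$fork_token, model = "time_model",
                   delta_bic = cmp$bic_time - pmin(cmp$bic_time, cmp$bic_no_time),
                   r2 = cmp$r2_time),
    tibble::tibble(fork_token = cmp$fork_token, model = "no_time_model",
                   delta_bic = cmp$bic_no_time - pmin(cmp$bic_time, cmp$bic_no_time),
                   r2 = cmp$r2_no_time)
  )
  long <- tidyr::pivot_longer(long, c("delta_bic", "r2"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = fork_token, y = value,
                                     colour = model, group = model)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot the condition difference smooth with significant windows
#'
#' @param ds a [difference_smooth()] result.
#' @return A ggplot object.
#' @export
plot_difference_smooth <- function(ds) {
  stopifnot(inherits(ds, "difference_smooth"))
  p <- ggplot2::ggplot(ds$curve, ggplot2::aes(x = t, y = diff_hat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "trial time (ms)",
                  y = "Visual - Audiovisual pupil change (mm)") +
    ggplot2::theme_minimal()
  if (nrow(ds$significant_windows)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(ds$significant_windows$start, ds$significant_windows$end),
      linetype = 3)
  }
  p
}

#' Plot per-participant missing percentage with the 30% cutoff
#'
#' @param diag a [diagnostics()] result.
#' @return A ggplot object.
#' @export
plot_missingness <- function(diag) {
  stopifnot(inherits(diag, "pupil_diagnostics"))
  ggplot2::ggplot(diag$missingness,
                  ggplot2::aes(x = factor(participant_id),
                               y = 100 * missing_frac)) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::geom_hline(yintercept = 30, colour = "red") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "participant", y = "% missing") +
    ggplot2::theme_minimal()
}

#' Plot per-participant blink counts across the four pre-gap variants
#'
#' @param diag a [diagnostics()] result.
#' @return A ggplot object.
#' @export
plot_blink_counts <- function(diag) {
  stopifnot(inherits(diag, "pupil_diagnostics"))
  ggplot2::ggplot(diag$blink_counts,
                  ggplot2::aes(x = factor(participant_id), y = n_blinks)) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "participant", y = "blink count") +
    ggplot2::theme_minimal()
}
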
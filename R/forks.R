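fork_levels <- list(
  extreme_filter = c("all_values", "trimmed"),
  aoi_filter = c("whole_screen", "aoi_only"),
  gap_handling = c("exclude", "interpolate"),
  baseline_ms = c(16, 100, 200),
  participant_rule = c("include_all", "exclude_high_missing")
)

token_map <- list(
  extreme_filter = c(all_values = "all", trimmed = "trimmed"),
  aoi_filter = c(whole_screen = "screen", aoi_only = "aoi"),
  gap_handling = c(exclude = "excl", interpolate = "interp"),
  participant_rule = c(include_all = "incl", exclude_high_missing = "excl")
)

#' One point in the preprocessing lattice
#'
#' @param extreme_filter `"all_values"` or `"trimmed"` (2-8 mm trimming).
#' @param aoi_filter `"whole_screen"` or `"aoi_only"`.
#' @param gap_handling `"exclude"` or `"interpolate"`.
#' @param baseline_ms baseline window length: 16, 100 or 200 ms.
#' @param participant_rule `"include_all"` or `"exclude_high_missing"`.
#' @return A `fork_spec` list.
#' @export
fork_spec <- function(extreme_filter = "all_values",
                      aoi_filter = "whole_screen",
                      gap_handling = "exclude",
                      baseline_ms = 16,
                      participant_rule = "include_all") {
  extreme_filter <- match.arg(extreme_filter, fork_levels$extreme_filter)
  aoi_filter <- match.arg(aoi_filter, fork_levels$aoi_filter)
  gap_handling <- match.arg(gap_handling, fork_levels$gap_handling)
  if (!baseline_ms %in% fork_levels$baseline_ms) {
    stop_config("baseline_ms must be one of 16, 100, 200")
  }
  participant_rule <- match.arg(participant_rule, fork_levels$participant_rule)
  structure(list(extreme_filter = extreme_filter, aoi_filter = aoi_filter,
                 gap_handling = gap_handling, baseline_ms = baseline_ms,
                 participant_rule = participant_rule),
            class = "fork_spec")
}

#' Enumerate the full 2 x 2 x 2 x 3 x 2 = 48 fork lattice
#'
#' @return A tibble with one row per fork, in a fixed deterministic order.
#' @export
fork_grid <- function() {
  g <- tidyr::expand_grid(
    extreme_filter = fork_levels$extreme_filter,
    aoi_filter = fork_levels$aoi_filter,
    gap_handling = fork_levels$gap_handling,
    baseline_ms = fork_levels$baseline_ms,
    participant_rule = fork_levels$participant_rule
  )
  g$fork_token <- vapply(seq_len(nrow(g)), function(i) {
    fork_token(fork_spec(g$extreme_filter[i], g$aoi_filter[i],
                         g$gap_handling[i], g$baseline_ms[i],
                         g$participant_rule[i]))
  }, character(1))
  g
}

#' Serialize a fork as a short token, e.g. `"trimmed|aoi|interp|100|excl"`
#'
#' @param fork a [fork_spec()].
#' @return A character scalar.
#' @export
fork_token <- function(fork) {
  stopifnot(inherits(fork, "fork_spec"))
  paste(token_map$extreme_filter[[fork$extreme_filter]],
        token_map$aoi_filter[[fork$aoi_filter]],
        token_map$gap_handling[[fork$gap_handling]],
        fork$baseline_ms,
        token_map$participant_rule[[fork$participant_rule]],
        sep = "|")
}

#' Parse a fork token back into a fork specification
#'
#' @param token a token produced by [fork_token()].
#' @return A [fork_spec()].
#' @export
parse_fork_token <- function(token) {
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5) stop_config(paste0("malformed fork token: ", token))
  inv <- function(map, x) {
    hit <- names(map)[map == x]
    if (!length(hit)) stop_config(paste0("unknown fork level: ", x))
    hit
  }
  fork_spec(inv(token_map$extreme_filter, parts[1]),
            inv(token_map$aoi_filter, parts[2]),
            inv(token_map$gap_handling, parts[3]),
            as.numeric(parts[4]),
            inv(token_map$participant_rule, parts[5]))
}

#' @export
format.fork_spec <- function(x, ...) fork_token(x)

#' @export
print.fork_spec <- function(x, ...) {
  cat("<fork_spec>", fork_token(x), "\n")
  invisible(x)
}
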
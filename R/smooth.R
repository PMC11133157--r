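#' Estimated condition difference over trial time
#'
#' For a time-model fit, evaluates the Visual - Audiovisual difference
#' `beta + f_visual(t) - f_audiovisual(t)` on a grid of trial times, with
#' pointwise SEs from the model-based coefficient covariance, a Wald
#' confidence band, and the maximal contiguous windows in which the band
#' excludes zero.
#'
#' @param fit a `pupil_fit` from the time model.
#' @param t_grid evaluation times (ms); default 101 equally spaced points
#'   over the fitted trial window.
#' @return A `difference_smooth` object: tibble `curve` (t, diff_hat,
#'   diff_se, ci_low, ci_high) and tibble `significant_windows` (start, end).
#' @export
difference_smooth <- function(fit, t_grid = NULL) {
  stopifnot(inherits(fit, "pupil_fit"))
  if (fit$spec$kind != "time_model") {
    stop_spec("difference_smooth requires a time_model fit")
  }
  if (is.null(t_grid)) {
    t_grid <- seq(fit$trange[1], fit$trange[2], length.out = 101)
  }
  sm_vis <- fit$colmap$smooths$g1_visual
  sm_av <- fit$colmap$smooths$g1_audiovisual
  bas <- bspline_basis(t_grid, sm_vis$k, degree = sm_vis$degree,
                       trange = sm_vis$trange)
  p <- length(fit$coefficients)
  Rmat <- matrix(0, length(t_grid), p)
  Rmat[, fit$colmap$beta] <- 1
  Rmat[, sm_vis$idx] <- bas$B %*% sm_vis$Q
  Rmat[, sm_av$idx] <- -(bas$B %*% sm_av$Q)
  diff_hat <- drop(Rmat %*% fit$coefficients)
  diff_se <- sqrt(pmax(rowSums((Rmat %*% fit$coef_cov) * Rmat), 0))
  z <- qnorm(1 - (1 - fit$ci_level) / 2)
  lo <- diff_hat - z * diff_se
  hi <- diff_hat + z * diff_se
  sig <- lo > 0 | hi < 0
  windows <- run_windows(t_grid, sig)
  structure(list(
    curve = tibble::tibble(t = t_grid, diff_hat = diff_hat, diff_se = diff_se,
                           ci_low = lo, ci_high = hi, significant = sig),
    significant_windows = windows,
    ci_level = fit$ci_level
  ), class = "difference_smooth")
}

run_windows <- function(t, flag) {
  if (!any(flag)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(start = t[starts[keep]], end = t[ends[keep]])
}

#' @export
print.difference_smooth <- function(x, ...) {
  cat("<difference_smooth>", nrow(x$curve), "grid points;",
      nrow(x$significant_windows), "significant window(s)\n")
  if (nrow(x$significant_windows)) {
    for (i in seq_len(nrow(x$significant_windows))) {
      cat(sprintf("  [%.0f, %.0f] ms\n", x$significant_windows$start[i],
                  x$significant_windows$end[i]))
    }
  }
  invisible(x)
}
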
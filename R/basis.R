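#' Cubic B-spline basis over equally spaced knots
#'
#' Evaluates `k` B-spline basis functions of the given degree over
#' breakpoints equally spaced on `[min(t), max(t)]` (clamped end knots, so
#' the rows form a partition of unity and `k = degree + 1` reduces to the
#' Bernstein basis). Times are internally rescaled to `[0, 1]`, which leaves
#' the basis values unchanged but keeps the penalty well scaled.
#'
#' @param t evaluation times (ms).
#' @param k number of basis functions (`k >= degree + 1`).
#' @param degree spline degree (default cubic).
#' @param trange optional range to span instead of `range(t)` (used when
#'   predicting at new times with a basis built on data).
#' @return A list: `B` (length(t) x k matrix), `knots` (on the 0-1 scale),
#'   `greville` (Greville abscissae), `trange`, `degree`.
#' @export
bspline_basis <- function(t, k, degree = 3, trange = NULL) {
  if (k < degree + 1) stop_config("k must be >= degree + 1")
  if (!length(t)) stop_config("t must be non-empty")
  if (is.null(trange)) trange <- range(t)
  if (diff(trange) <= 0) stop_config("degenerate t range")
  x <- (t - trange[1]) / diff(trange)
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    stop_domain("evaluation times outside the basis range")
  }
  x <- pmin(pmax(x, 0), 1)
  inner <- seq(0, 1, length.out = k - degree + 1)
  knots <- c(rep(0, degree), inner, rep(1, degree))
  ord <- degree + 1
  # clamp x strictly below the right end for splineDesign, then fix the
  # boundary row analytically (rightmost basis function equals 1 at x = 1)
  at_end <- x >= 1 - 1e-12
  xs <- ifelse(at_end, 1 - 1e-9, x)
  B <- splines::splineDesign(knots, xs, ord = ord)
  if (any(at_end)) {
    B[at_end, ] <- 0
    B[at_end, k] <- 1
  }
  grev <- vapply(seq_len(k), function(j) mean(knots[(j + 1):(j + degree)]),
                 numeric(1))
  list(B = B, knots = knots, greville = grev, trange = trange, degree = degree)
}

# Difference penalty of the given order built from divided differences over
# the Greville abscissae, so its null space is exactly the polynomials of
# degree < order in t. Scaled to O(1) diagonal for a comparable lambda range.
difference_penalty <- function(greville, order = 2) {
  k <- length(greville)
  if (order >= k) stop_config("penalty order must be < k")
  D <- diag(k)
  xi <- greville
  for (m in seq_len(order)) {
    rows <- nrow(D) - 1
    step <- (xi[(m + 1):k] - xi[seq_len(k - m)]) / m
    D1 <- matrix(0, rows, nrow(D))
    for (i in seq_len(rows)) {
      D1[i, i] <- -1 / step[i]
      D1[i, i + 1] <- 1 / step[i]
    }
    D <- D1 %*% D
  }
  S <- crossprod(D)
  S / mean(diag(S))
}

# Orthonormal basis of the penalty null space (polynomials of degree < order
# evaluated at the Greville abscissae).
penalty_nullspace <- function(greville, order = 2) {
  N <- outer(greville, seq_len(order) - 1, `^`)
  qr.Q(qr(N))
}

# Sum-to-zero constraint: columns of Q span the null space of the given
# row-mean functionals (one per row of C), so B %*% Q has zero-mean fitted
# contributions over each row set used to build the constraint.
constraint_matrix <- function(C) {
  C <- rbind(C)
  dec <- qr(t(C))
  r <- dec$rank
  qr.Q(dec, complete = TRUE)[, -seq_len(r), drop = FALSE]
}
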
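#' Specification of one of the two competing models
#'
#' `time_model`: pupil change = intercept + block effect + one penalized
#' spline of trial time per block level (sum-to-zero constrained, its own
#' smoothing parameter each) + one factor-smooth term of trial time per
#' participant (a ridge-penalized participant level plus a block-balanced
#' smooth deviation), all participants sharing one wiggliness and one
#' level smoothing parameter.
#'
#' `no_time_model`: intercept + block effect + ridge-penalized
#' participant-by-block cell effects sharing one smoothing parameter.
#'
#' @param kind `"time_model"` or `"no_time_model"`.
#' @param k_basis number of B-spline basis functions per smooth (>= 4).
#' @param penalty_order difference-penalty order (default 2: wiggliness
#'   beyond a straight line is penalized).
#' @param lambda_grid positive log-spaced candidate smoothing parameters for
#'   GCV selection.
#' @param gcv_gamma GCV inflation factor (see [penalized_fit()]); the
#'   default 1.4 is the customary guard against GCV undersmoothing, which
#'   matters here because baseline correction leaves trial-level residual
#'   dependence.
#' @param ci_level coverage of reported confidence intervals.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("time_model", "no_time_model"),
                       k_basis = 20, penalty_order = 2,
                       lambda_grid = 10^seq(-4, 6, length.out = 11),
                       gcv_gamma = 1.4, ci_level = 0.95) {
  kind <- match.arg(kind)
  if (k_basis < 4) stop_config("k_basis must be >= 4")
  if (penalty_order >= k_basis) stop_config("penalty_order must be < k_basis")
  if (any(lambda_grid <= 0)) stop_config("lambda_grid must be positive")
  if (ci_level <= 0 || ci_level >= 1) stop_config("ci_level must be in (0, 1)")
  if (gcv_gamma < 1) stop_config("gcv_gamma must be >= 1")
  structure(list(kind = kind, k_basis = as.integer(k_basis),
                 penalty_order = as.integer(penalty_order),
                 lambda_grid = sort(lambda_grid), gcv_gamma = gcv_gamma,
                 ci_level = ci_level),
            class = "model_spec")
}

#' Build the design matrix and penalty blocks for a model
#'
#' Returns the dense design matrix, the penalized blocks (column indices,
#' penalty matrix on those columns, and the smoothing-parameter group each
#' block belongs to), and a column map describing where the intercept, the
#' block indicator and every smooth live (with the information needed to
#' evaluate smooths at new times).
#'
#' @param dataset a [processed_dataset()] with both blocks and >= 2
#'   participants.
#' @param spec a [model_spec()].
#' @return A list: `X`, `y`, `blocks`, `colmap`, `n_groups`, `cluster`
#'   (trial cluster ids for robust covariance).
#' @export
build_design <- function(dataset, spec) {
  stopifnot(inherits(dataset, "processed_dataset"), inherits(spec, "model_spec"))
  if (isTRUE(dataset$degenerate)) {
    stop_fit(paste0("degenerate dataset",
                    if (!is.null(dataset$fork)) paste0(" [", fork_token(dataset$fork), "]")))
  }
  dat <- dataset$data
  if (length(unique(dat$block)) < 2) stop_spec("both block levels must be present")
  if (length(unique(dat$participant_id)) < 2) stop_spec("need >= 2 participants")

  n <- nrow(dat)
  xvis <- as.numeric(dat$block == "visual")
  X <- cbind(`(Intercept)` = rep(1, n), block_visual = xvis)
  colmap <- list(alpha = 1L, beta = 2L, smooths = list())
  blocks <- list()
  trange <- range(dat$t_trial)

  if (spec$kind == "time_model") {
    k <- spec$k_basis
    bas <- bspline_basis(dat$t_trial, k, trange = trange)
    S_diff <- difference_penalty(bas$greville, spec$penalty_order)
    Nmat <- penalty_nullspace(bas$greville, spec$penalty_order)
    # condition smooths: one per block level, own lambda group each
    grp <- 0L
    for (lev in c("audiovisual", "visual")) {
      grp <- grp + 1L
      rows <- dat$block == lev
      Bl <- bas$B * rows
      Q <- constraint_matrix(colMeans(bas$B[rows, , drop = FALSE]))
      Z <- Bl %*% Q
      idx <- ncol(X) + seq_len(ncol(Z))
      X <- cbind(X, Z)
      blocks[[length(blocks) + 1]] <- list(
        idx = idx, S = crossprod(Q, S_diff %*% Q), group = grp)
      colmap$smooths[[paste0("g1_", lev)]] <- list(
        term = "condition", level = lev, idx = idx, Q = Q,
        trange = trange, k = k, degree = bas$degree)
    }
    # participant smooths (factor-smooth analog), shared across participants
    # through two lambda groups, as in standard factor-smooth practice: one
    # for wiggliness (difference penalty) and one ridge for the penalty null
    # space plus a per-participant intercept, since random-curve amplitude
    # and random-level amplitude are genuinely different variance scales.
    # Each smooth deviation is constrained to zero mean within each block's
    # rows of its participant, so participant terms cannot shift block means
    # and beta stays the mean Visual - Audiovisual contrast even when GCV
    # selects a near-zero smoothing parameter.
    grp_w <- grp + 1L
    grp_n <- grp + 2L
    for (pid in sort(unique(dat$participant_id))) {
      rows <- dat$participant_id == pid
      Bl <- bas$B * rows
      Cp <- rbind(
        colMeans(bas$B[rows & dat$block == "audiovisual", , drop = FALSE]),
        colMeans(bas$B[rows & dat$block == "visual", , drop = FALSE])
      )
      Cp <- Cp[is.finite(rowSums(Cp)), , drop = FALSE]
      Q <- constraint_matrix(Cp)
      Z <- cbind(as.numeric(rows), Bl %*% Q)
      idx <- ncol(X) + seq_len(ncol(Z))
      X <- cbind(X, Z)
      Sw <- matrix(0, ncol(Z), ncol(Z))
      Sw[-1, -1] <- crossprod(Q, S_diff %*% Q)
      Sn <- matrix(0, ncol(Z), ncol(Z))
      Sn[1, 1] <- 1
      Sn[-1, -1] <- crossprod(Q, tcrossprod(Nmat) %*% Q)
      blocks[[length(blocks) + 1]] <- list(idx = idx, S = Sw, group = grp_w)
      blocks[[length(blocks) + 1]] <- list(idx = idx, S = Sn, group = grp_n)
      colmap$smooths[[paste0("g2_id", pid)]] <- list(
        term = "participant", level = pid, idx = idx, Q = Q,
        trange = trange, k = k, degree = bas$degree)
    }
    n_groups <- grp_n
  } else {
    cell <- interaction(dat$participant_id, dat$block, drop = TRUE)
    M <- stats::model.matrix(~ 0 + cell)
    colnames(M) <- paste0("cell_", levels(cell))
    idx <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
    blocks[[1]] <- list(idx = idx, S = diag(ncol(M)), group = 1L)
    colmap$smooths[["g1_cells"]] <- list(term = "cells", idx = idx,
                                         levels = levels(cell))
    n_groups <- 1L
  }

  list(X = X, y = dat$y, blocks = blocks, colmap = colmap,
       n_groups = n_groups,
       cluster = paste(dat$participant_id, dat$block, dat$trial),
       trange = trange)
}
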
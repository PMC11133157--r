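# ---- penalized least-squares engine ----------------------------------------

embed_penalty <- function(block, p) {
  S <- matrix(0, p, p)
  S[block$idx, block$idx] <- block$S
  S
}

# Solve (X'X + sum_g lambda_g S_g) theta = X'y from precomputed cross
# products; returns coefficients, edf, rss and the inverse for covariances.
pls_solve <- function(XtX, Xty, yty, n, Sg, lambda, want_inverse = FALSE) {
  A <- XtX
  for (g in seq_along(Sg)) A <- A + lambda[g] * Sg[[g]]
  R <- tryCatch(chol(A), error = function(e) {
    chol(A + diag(1e-8 * mean(diag(A)), nrow(A)))
  })
  Ainv <- chol2inv(R)
  theta <- drop(Ainv %*% Xty)
  edf <- sum(Ainv * XtX)
  rss <- max(yty - 2 * sum(theta * Xty) + drop(crossprod(theta, XtX %*% theta)),
             0)
  out <- list(theta = theta, edf = edf, rss = rss)
  if (want_inverse) out$Ainv <- Ainv
  out
}

gcv_score <- function(rss, edf, n, gamma = 1) {
  denom <- max(n - gamma * edf, 1e-8)
  n * rss / denom^2
}

#' Penalized least squares with GCV-selected smoothing parameters
#'
#' Minimizes `||y - X theta||^2 + sum_g lambda_g theta' S_g theta`.
#' Smoothing parameters are chosen by minimizing the generalized
#' cross-validation score `n RSS / (n - edf)^2` over `lambda_grid` by
#' coordinate descent (one grid pass per parameter group per sweep, until
#' the score change falls below 1e-6 relative or 25 sweeps). Passing
#' `lambda` fixes the smoothing parameters (recycled over groups), which
#' with `lambda = 0` reproduces ordinary least squares on full-rank designs.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param blocks list of penalty blocks: each a list with `idx` (columns),
#'   `S` (penalty on those columns) and `group` (smoothing-parameter group).
#' @param lambda_grid candidate smoothing parameters (log-spaced, positive).
#' @param lambda optional fixed smoothing parameters, one per group.
#' @param gamma GCV inflation factor; values above 1 (1.4 is the customary
#'   choice in additive modelling) discourage the undersmoothing GCV is
#'   prone to when residuals are serially dependent.
#' @return A list: `theta`, `lambda`, `edf`, `rss`, `gcv`, `Ainv`, `n`.
#' @export
penalized_fit <- function(X, y, blocks = list(),
                          lambda_grid = 10^seq(-4, 6, length.out = 11),
                          lambda = NULL, gamma = 1) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  groups <- if (length(blocks)) max(vapply(blocks, `[[`, 1L, "group")) else 0L
  Sg <- vector("list", groups)
  if (groups > 0) {
    for (g in seq_len(groups)) Sg[[g]] <- matrix(0, p, p)
    for (b in blocks) Sg[[b$group]] <- Sg[[b$group]] + embed_penalty(b, p)
  }

  if (groups == 0L) {
    sol <- pls_solve(XtX, Xty, yty, n, list(), numeric(0), want_inverse = TRUE)
    return(c(sol, list(lambda = numeric(0),
                       gcv = gcv_score(sol$rss, sol$edf, n, gamma), n = n)))
  }

  if (!is.null(lambda)) {
    lam <- rep_len(lambda, groups)
    sol <- pls_solve(XtX, Xty, yty, n, Sg, lam, want_inverse = TRUE)
    return(c(sol, list(lambda = lam,
                       gcv = gcv_score(sol$rss, sol$edf, n, gamma), n = n)))
  }

  grid <- sort(lambda_grid)
  lam <- rep(grid[ceiling(length(grid) / 2)], groups)
  best <- pls_solve(XtX, Xty, yty, n, Sg, lam)
  gcv_prev <- gcv_score(best$rss, best$edf, n, gamma)
  for (sweep in seq_len(25)) {
    for (g in seq_len(groups)) {
      scores <- vapply(grid, function(lg) {
        lam_try <- lam
        lam_try[g] <- lg
        s <- pls_solve(XtX, Xty, yty, n, Sg, lam_try)
        gcv_score(s$rss, s$edf, n, gamma)
      }, numeric(1))
      lam[g] <- grid[which.min(scores)]
    }
    sol <- pls_solve(XtX, Xty, yty, n, Sg, lam)
    gcv_now <- gcv_score(sol$rss, sol$edf, n, gamma)
    if (abs(gcv_prev - gcv_now) < 1e-6 * (abs(gcv_prev) + 1e-12)) break
    gcv_prev <- gcv_now
  }
  sol <- pls_solve(XtX, Xty, yty, n, Sg, lam, want_inverse = TRUE)
  c(sol, list(lambda = lam, gcv = gcv_score(sol$rss, sol$edf, n, gamma), n = n))
}

# ---- model fitting ----------------------------------------------------------

#' Fit one of the two competing models to a processed dataset
#'
#' Coefficients minimize the penalized sum of squares; smoothing parameters
#' are selected by GCV (see [penalized_fit()]). The report includes the
#' Gaussian log-likelihood at the MLE residual variance, effective degrees
#' of freedom (trace of the hat matrix), `BIC = -2 loglik + (edf + 1) log n`
#' (the +1 counts the residual scale), adjusted R-squared, and the
#' familiarization-block coefficient (Visual - Audiovisual) with its
#' confidence interval.
#'
#' Because the per-trial subtractive baseline induces trial-level residual
#' dependence, the block coefficient's SE and CI use a trial-clustered
#' sandwich covariance (CR1 correction, normal quantile); the model-based
#' covariance `sigma^2 (X'X + sum lambda S)^-1` is retained in `coef_cov`
#' and drives the smooth confidence bands. Set `cluster = "none"` for the
#' plain model-based SE.
#'
#' Participants with fewer than 10 rows in the dataset are dropped from the
#' fit with a warning.
#'
#' @param dataset a [processed_dataset()].
#' @param spec a [model_spec()].
#' @param lambda optional fixed smoothing parameters (bypasses GCV).
#' @param cluster `"trial"` (default) or `"none"`: clustering for the block
#'   coefficient's sandwich SE.
#' @return A `pupil_fit` object.
#' @export
fit_model <- function(dataset, spec = model_spec(), lambda = NULL,
                      cluster = c("trial", "none")) {
  cluster <- match.arg(cluster)
  stopifnot(inherits(dataset, "processed_dataset"))
  tabn <- table(dataset$data$participant_id)
  thin <- names(tabn)[tabn < 10]
  if (length(thin)) {
    warning("dropping participant(s) with < 10 rows: ",
            paste(thin, collapse = ", "))
    dataset$data <- dataset$data[!dataset$data$participant_id %in%
                                   as.integer(thin), , drop = FALSE]
    dataset <- processed_dataset(dataset$data, dataset$fork,
                                 dataset$provenance)
  }
  des <- build_design(dataset, spec)
  n <- length(des$y)
  if (n <= 1) stop_fit("need more than one observation")

  fit <- penalized_fit(des$X, des$y, des$blocks,
                       lambda_grid = spec$lambda_grid, lambda = lambda,
                       gamma = spec$gcv_gamma)
  theta <- fit$theta
  rss <- fit$rss
  edf <- fit$edf
  sigma2 <- rss / max(n - edf, 1e-8)
  coef_cov <- sigma2 * fit$Ainv

  resid <- des$y - drop(des$X %*% theta)
  if (cluster == "trial") {
    robust_cov <- cluster_sandwich(des$X, resid, des$cluster, fit$Ainv)
  } else {
    robust_cov <- coef_cov
  }

  beta_hat <- theta[des$colmap$beta]
  beta_se <- sqrt(robust_cov[des$colmap$beta, des$colmap$beta])
  z <- qnorm(1 - (1 - spec$ci_level) / 2)
  beta_ci <- c(beta_hat - z * beta_se, beta_hat + z * beta_se)

  sigma2_ml <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  k_params <- edf + 1
  bic <- -2 * loglik + k_params * log(n)

  tss <- sum((des$y - mean(des$y))^2)
  if (tss <= 0) stop_domain("zero total variance in y")
  r2 <- 1 - (rss / max(n - edf, 1e-8)) / (tss / (n - 1))

  structure(list(
    spec = spec,
    fork = dataset$fork,
    alpha_hat = theta[des$colmap$alpha],
    beta_hat = beta_hat,
    beta_se = beta_se,
    beta_ci = beta_ci,
    coefficients = theta,
    smooth_coefs = lapply(des$colmap$smooths, function(s) theta[s$idx]),
    lambdas = fit$lambda,
    edf = edf,
    loglik = loglik,
    n = n,
    k_params = k_params,
    bic = bic,
    r2 = r2,
    coef_cov = coef_cov,
    robust_cov = robust_cov,
    residual_sd = sqrt(sigma2),
    fitted = drop(des$X %*% theta),
    y = des$y,
    rss = rss,
    gcv = fit$gcv,
    colmap = des$colmap,
    trange = des$trange,
    ci_level = spec$ci_level
  ), class = "pupil_fit")
}

cluster_sandwich <- function(X, resid, cluster, Ainv) {
  ids <- split(seq_along(resid), cluster)
  p <- ncol(X)
  M <- matrix(0, p, p)
  for (idx in ids) {
    u <- drop(crossprod(X[idx, , drop = FALSE], resid[idx]))
    M <- M + tcrossprod(u)
  }
  m <- length(ids)
  corr <- if (m > 1) m / (m - 1) else 1
  corr * Ainv %*% M %*% Ainv
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat("<pupil_fit>", x$spec$kind, "\n")
  cat(sprintf("  n = %d, edf = %.1f, BIC = %.1f, adj R2 = %.3f\n",
              x$n, x$edf, x$bic, x$r2))
  cat(sprintf("  block (Visual - Audiovisual): %.4f mm [%.4f, %.4f]\n",
              x$beta_hat, x$beta_ci[1], x$beta_ci[2]))
  invisible(x)
}

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 loglik + k log(n)` with `k = edf + 1` (effective degrees of
#' freedom plus the residual scale).
#'
#' @param fit a `pupil_fit`.
#' @return BIC, a scalar.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "pupil_fit"))
  if (fit$n <= 1) stop_domain("BIC requires n > 1")
  -2 * fit$loglik + fit$k_params * log(fit$n)
}

#' Evidence label for a BIC difference
#'
#' Delta BIC (candidate minus best): below 2 is weak evidence, 2-6
#' positive, 6-10 strong, above 10 very strong evidence in favour of the
#' lower-BIC model.
#'
#' @param delta non-negative BIC difference(s).
#' @return Character vector of labels.
#' @export
delta_bic_label <- function(delta) {
  if (any(delta < 0)) stop_domain("delta BIC must be >= 0")
  cut(delta, breaks = c(-Inf, 2, 6, 10, Inf), right = FALSE,
      labels = c("weak", "positive", "strong", "very strong")) |>
    as.character()
}

#' Adjusted R-squared of a fit
#'
#' `1 - (RSS / (n - edf)) / (TSS / (n - 1))`.
#'
#' @param fit a `pupil_fit`.
#' @return Adjusted R-squared.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "pupil_fit"))
  fit$r2
}
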
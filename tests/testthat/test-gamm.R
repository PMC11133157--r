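test_that("B-spline basis is a partition of unity and reduces to Bernstein", {
  t <- seq(0, 1000, length.out = 73)
  for (k in c(4, 7, 20)) {
    B <- bspline_basis(t, k)$B
    expect_equal(rowSums(B), rep(1, length(t)), tolerance = 1e-12)
    expect_true(all(B >= -1e-12))
  }
  # k = 4, degree 3 on [0, 1]: Bernstein cubics
  x <- c(0, 0.25, 0.5, 1)
  B4 <- bspline_basis(x, 4)$B
  bern <- cbind((1 - x)^3, 3 * x * (1 - x)^2, 3 * x^2 * (1 - x), x^3)
  expect_equal(B4, bern, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(B4[1, ], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_error(bspline_basis(rep(1, 5), 4), class = "pv_config_error")
  expect_error(bspline_basis(numeric(0), 4), class = "pv_config_error")
})

test_that("basis evaluation matches an independent Cox-de Boor recursion", {
  for (k in c(5, 9, 14)) {
    bas <- bspline_basis(seq(0, 900, by = 60), k)
    x <- (seq(0, 900, by = 60) - bas$trange[1]) / diff(bas$trange)
    # include the knot positions themselves among evaluation points
    x <- sort(unique(c(x, bas$knots[bas$knots > 0 & bas$knots < 1])))
    B_pkg <- bspline_basis(x * diff(bas$trange) + bas$trange[1], k,
                           trange = bas$trange)$B
    B_ora <- cox_de_boor_basis(x, k, 3, bas$knots)
    expect_equal(B_pkg, B_ora, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("zero-penalty fits equal the normal-equations OLS oracle", {
  set.seed(1)
  n <- 200
  X <- cbind(1, matrix(rnorm(n * 9), n))
  y <- drop(X %*% runif(10, -1, 1)) + rnorm(n)
  blocks <- list(list(idx = 3:10, S = diag(8), group = 1L))
  f0 <- penalized_fit(X, y, blocks, lambda = 0)
  expect_equal(f0$theta, ols_oracle(X, y), tolerance = 1e-8)
  expect_equal(f0$edf, 10, tolerance = 1e-6)
  # known ridge penalty: closed form
  lam <- 3.7
  f1 <- penalized_fit(X, y, blocks, lambda = lam)
  S <- diag(c(rep(0, 2), rep(1, 8)))
  expect_equal(f1$theta, drop(solve(crossprod(X) + lam * S, crossprod(X, y))),
               tolerance = 1e-8)
})

test_that("RSS is non-decreasing in each smoothing parameter", {
  set.seed(2)
  n <- 150
  t <- runif(n, 0, 1000)
  y <- sin(t / 150) + rnorm(n, 0, 0.3)
  bas <- bspline_basis(t, 10)
  X <- cbind(1, bas$B)
  S <- difference_penalty(bas$greville, 2)
  blocks <- list(list(idx = 2:11, S = S, group = 1L))
  rss <- vapply(10^seq(-4, 6, by = 1), function(l) {
    penalized_fit(X, y, blocks, lambda = l)$rss
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8))
})

test_that("an infinitely smoothed difference-penalty term becomes linear in t", {
  set.seed(3)
  n <- 300
  t <- runif(n, 0, 1000)
  y <- 2 + 0.003 * t + sin(t / 100) + rnorm(n, 0, 0.2)
  bas <- bspline_basis(t, 12)
  X <- cbind(1, bas$B)
  S <- difference_penalty(bas$greville, 2)
  f <- penalized_fit(X, y, list(list(idx = 2:13, S = S, group = 1L)),
                     lambda = 1e10)
  contrib <- drop(bas$B %*% f$theta[2:13])
  lin <- lm(contrib ~ t)
  expect_gt(summary(lin)$r.squared, 0.999999)
})

test_that("design bookkeeping matches the two model structures", {
  tab <- tiny_session(seed = 51, n_participants = 4, high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  tok <- vapply(mv, function(d) fork_token(d$fork), character(1))
  ds <- mv[[which(tok == "trimmed|screen|excl|100|incl")]]
  P <- length(unique(ds$data$participant_id))

  des_t <- build_design(ds, model_spec("time_model", k_basis = 12))
  sm <- des_t$colmap$smooths
  expect_identical(sum(vapply(sm, function(s) s$term == "condition",
                              logical(1))), 2L)
  expect_identical(sum(vapply(sm, function(s) s$term == "participant",
                              logical(1))), P)
  expect_identical(des_t$colmap$alpha, 1L)
  expect_identical(des_t$colmap$beta, 2L)
  # condition smooths: k - 1 columns; participant terms: level + k - 2
  expect_identical(length(sm$g1_visual$idx), 11L)
  expect_identical(length(sm[[paste0("g2_id", ds$data$participant_id[1])]]$idx),
                   11L)
  # sum-to-zero: each condition smooth's fitted contribution has mean 0 on
  # its level's rows, for arbitrary coefficients
  f <- fit_model(ds, model_spec("time_model", k_basis = 12))
  for (lev in c("audiovisual", "visual")) {
    s <- des_t$colmap$smooths[[paste0("g1_", lev)]]
    contrib <- drop(des_t$X[, s$idx] %*% runif(length(s$idx)))
    expect_equal(mean(contrib[ds$data$block == lev]), 0, tolerance = 1e-10)
  }

  des_n <- build_design(ds, model_spec("no_time_model"))
  expect_identical(length(des_n$blocks), 1L)
  expect_identical(length(des_n$blocks[[1]]$idx), 2L * P)
  expect_identical(ncol(des_n$X), 2L + 2L * P)

  # a block level missing is a specification error
  one_block <- ds$data[ds$data$block == "visual", ]
  expect_error(
    build_design(structure(list(data = one_block, degenerate = FALSE),
                           class = "processed_dataset"),
                 model_spec("time_model")),
    class = "pv_spec_error")
})

test_that("BIC follows its defining identity and evidence bands", {
  tab <- tiny_session(seed = 52, n_participants = 3, high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  ds <- mv[[which(vapply(mv, function(d) fork_token(d$fork), character(1)) ==
                    "trimmed|screen|interp|100|incl")]]
  for (kind in c("time_model", "no_time_model")) {
    f <- fit_model(ds, model_spec(kind, k_basis = 8))
    expect_equal(f$bic, -2 * f$loglik + f$k_params * log(f$n),
                 tolerance = 1e-12)
    expect_equal(bic(f), f$bic)
    expect_equal(f$k_params, f$edf + 1)
    expect_lte(f$r2, 1)
    expect_true(f$beta_ci[1] <= f$beta_hat && f$beta_hat <= f$beta_ci[2])
  }
  # loglik = -100, k = 5, n = e gives BIC = 205
  toy <- structure(list(loglik = -100, k_params = 5, n = exp(1)),
                   class = "pupil_fit")
  expect_equal(bic(toy), 205)
  expect_identical(delta_bic_label(c(0.5, 4, 8, 12)),
                   c("weak", "positive", "strong", "very strong"))
  expect_error(delta_bic_label(-1), class = "pv_domain_error")
})

test_that("adjusted R-squared matches its formula computed from the fit", {
  tab <- tiny_session(seed = 53, n_participants = 3, high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  ds <- mv[[which(vapply(mv, function(d) fork_token(d$fork), character(1)) ==
                    "trimmed|screen|excl|16|incl")]]
  f <- fit_model(ds, model_spec("no_time_model"))
  rss <- sum((f$y - f$fitted)^2)
  tss <- sum((f$y - mean(f$y))^2)
  expect_equal(f$rss, rss, tolerance = 1e-8)
  expect_equal(r_squared(f),
               1 - (rss / (f$n - f$edf)) / (tss / (f$n - 1)),
               tolerance = 1e-10)
})

test_that("duplicating every row leaves coefficients unchanged but moves BIC", {
  tab <- tiny_session(seed = 54, n_participants = 3, high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  ds <- mv[[which(vapply(mv, function(d) fork_token(d$fork), character(1)) ==
                    "trimmed|screen|excl|100|incl")]]
  dup_rows <- dplyr::bind_rows(
    ds$data,
    dplyr::mutate(ds$data, t_trial = t_trial + 0.001)  # keep the key unique
  )
  ds2 <- processed_dataset(dup_rows, ds$fork)
  lam <- c(10, 10, 10, 10)
  f1 <- fit_model(ds, model_spec("time_model", k_basis = 8), lambda = lam)
  f2 <- fit_model(ds2, model_spec("time_model", k_basis = 8), lambda = 2 * lam)
  expect_equal(f2$beta_hat, f1$beta_hat, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(f1$bic, f2$bic)))
  expect_identical(f2$n, 2L * f1$n)
})

test_that("difference smooth recovers the generating condition difference", {
  eff <- effect_early_late()
  tab <- tiny_session(seed = 55, n_participants = 4, effect = eff,
                      high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  ds <- mv[[which(vapply(mv, function(d) fork_token(d$fork), character(1)) ==
                    "trimmed|screen|interp|100|incl")]]
  f <- fit_model(ds, model_spec("time_model"))
  sm <- difference_smooth(f)
  expect_identical(nrow(sm$curve), 101L)
  truth <- true_difference(eff, sm$curve$t)
  expect_gt(cor(sm$curve$diff_hat, truth), 0.8)
  # windows are maximal runs where the band excludes zero
  sig <- sm$curve$ci_low > 0 | sm$curve$ci_high < 0
  expect_identical(sum(sig) > 0, nrow(sm$significant_windows) > 0)
  # no-time fits cannot produce a difference smooth
  fn <- fit_model(ds, model_spec("no_time_model"))
  expect_error(difference_smooth(fn), class = "pv_spec_error")
})

test_that("the fitted difference agrees with an independent mgcv fit", {
  skip_if_not_installed("mgcv")
  eff <- effect_early_late()
  tab <- tiny_session(seed = 56, n_participants = 4, effect = eff,
                      high_missing_ids = integer(0))
  mv <- build_multiverse(tab)
  ds <- mv[[which(vapply(mv, function(d) fork_token(d$fork), character(1)) ==
                    "trimmed|screen|excl|100|incl")]]
  f <- fit_model(ds, model_spec("time_model", k_basis = 10))
  dat <- ds$data
  dat$block <- factor(dat$block)
  dat$id <- factor(dat$participant_id)
  g <- mgcv::gam(y ~ block + s(t_trial, by = block, k = 10) +
                   s(t_trial, id, bs = "fs", k = 5),
                 data = dat, method = "REML")
  # compare the two condition-difference curves on a common grid
  grid <- seq(min(dat$t_trial), max(dat$t_trial), length.out = 60)
  nd_v <- data.frame(t_trial = grid, block = "visual", id = dat$id[1])
  nd_a <- data.frame(t_trial = grid, block = "audiovisual", id = dat$id[1])
  diff_mgcv <- predict(g, nd_v) - predict(g, nd_a)
  sm <- difference_smooth(f, grid)
  expect_gt(cor(sm$curve$diff_hat, diff_mgcv), 0.9)
  expect_lt(mean(abs(sm$curve$diff_hat - diff_mgcv)), 0.05)
})
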
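# Shared fixtures and independent oracles for the suite.

# Small, fast session (4 participants, one forced above 30% missingness).
tiny_session <- function(seed = 42, n_participants = 4,
                         effect = effect_early_late(),
                         high_missing_ids = 2L, ...) {
  cfg <- session_config(n_participants = n_participants, seed = seed,
                        high_missing_ids = high_missing_ids, ...)
  simulate_session(cfg, effect)
}

# A clean artifact-free table useful for exact-value checks.
clean_session <- function(seed = 7, n_participants = 2, noise_sd = 0,
                          effect = null_effect(participant_curve_sd = 0)) {
  cfg <- session_config(n_participants = n_participants, seed = seed,
                        noise_sd = noise_sd, blink_rate = 0,
                        trackloss_rate = 0, extreme_rate = 0,
                        tonic_sd_between = 0)
  simulate_session(cfg, effect)
}

# Hand-built monocular series for operator-level checks.
toy_series <- function(pupil, participant_id = 1L, block = "audiovisual",
                       trial = NULL, rate = 60) {
  n <- length(pupil)
  if (is.null(trial)) trial <- rep(1L, n)
  within_trial <- stats::ave(seq_len(n), trial, FUN = seq_along) - 1
  tibble::tibble(
    participant_id = as.integer(participant_id),
    block = block,
    trial = as.integer(trial),
    t_trial = unname(within_trial) * 1000 / rate,
    pupil = pupil
  )
}

# Independent Cox-de Boor recursion for B-spline evaluation (the oracle the
# package basis is checked against; deliberately naive and recursive).
cox_de_boor <- function(x, j, ord, knots) {
  if (ord == 1) {
    return(as.numeric(knots[j] <= x & x < knots[j + 1]))
  }
  d1 <- knots[j + ord - 1] - knots[j]
  d2 <- knots[j + ord] - knots[j + 1]
  t1 <- if (d1 > 0) (x - knots[j]) / d1 * cox_de_boor(x, j, ord - 1, knots) else 0
  t2 <- if (d2 > 0) (knots[j + ord] - x) / d2 *
    cox_de_boor(x, j + 1, ord - 1, knots) else 0
  t1 + t2
}

cox_de_boor_basis <- function(x, k, degree, knots) {
  ord <- degree + 1
  B <- sapply(seq_len(k), function(j) cox_de_boor(x, j, ord, knots))
  B <- matrix(B, nrow = length(x))
  # half-open support convention leaves the right boundary to the last basis
  at_end <- x >= knots[length(knots)] - 1e-12
  if (any(at_end)) {
    B[at_end, ] <- 0
    B[at_end, k] <- 1
  }
  B
}

# Ordinary least squares by explicit normal equations (oracle for the
# zero-penalty fits).
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
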
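#' Configuration for a synthetic familiarization session
#'
#' Describes one simulated eye-tracking session: a binocular recording of
#' `n_participants` infants, each completing two familiarization blocks
#' (audiovisual and visual) of `n_trials` consecutive trials of
#' `trial_duration` ms at `sampling_rate` Hz. Artifact rates control blinks
#' (short binocular gaps), trackloss (longer, possibly monocular gaps),
#' extreme-yet-plausible pupil values outside 2-8 mm, and gaze spill-over
#' outside the central area of interest.
#'
#' Defaults are chosen to resemble an infant 60 Hz recording: tonic pupil
#' around 4 mm with 0.4 mm between-participant SD, ~0.3 blinks/s lasting
#' 100-400 ms, ~8% of samples lost in longer runs, ~1% scattered extreme
#' samples just outside the 2-8 mm band (mostly low-side, as partial lid
#' occlusion shrinks the apparent pupil), and ~90% of gaze dwells inside
#' the AoI.
#'
#' @param n_participants number of participants.
#' @param sampling_rate sampling frequency in Hz.
#' @param n_trials trials per block (each block lasts `n_trials` seconds).
#' @param trial_duration trial length in ms.
#' @param tonic_mean,tonic_sd_between mean and between-participant SD of the
#'   tonic pupil level, mm.
#' @param noise_sd SD of the sample-level measurement noise, mm. 90% of the
#'   noise variance is shared between the two eyes, 10% is eye-specific, so
#'   the left/right correlation stays near physiological levels.
#' @param blink_rate expected blinks per second (Poisson starts per block).
#' @param blink_duration length-2 range of blink durations, ms.
#' @param trackloss_rate target fraction of samples lost in long runs.
#' @param extreme_rate fraction of observed samples replaced by values
#'   outside the 2-8 mm physiological band.
#' @param aoi_inside_prob probability that a gaze dwell falls inside the AoI.
#' @param high_missing_ids integer participant indices forced above 30%
#'   missingness (mirrors participants excluded by the missingness fork).
#' @param seed integer seed; all randomness flows from this one seed.
#' @return A `session_config` list.
#' @export
session_config <- function(n_participants = 8,
                           sampling_rate = 60,
                           n_trials = 9,
                           trial_duration = 1000,
                           tonic_mean = 4.0,
                           tonic_sd_between = 0.4,
                           noise_sd = 0.15,
                           blink_rate = 0.3,
                           blink_duration = c(100, 400),
                           trackloss_rate = 0.08,
                           extreme_rate = 0.01,
                           aoi_inside_prob = 0.9,
                           high_missing_ids = integer(0),
                           seed = 1L) {
  if (n_participants < 0) stop_config("n_participants must be >= 0")
  if (sampling_rate <= 0) stop_config("sampling_rate must be > 0")
  if (n_trials <= 0 || trial_duration <= 0) {
    stop_config("n_trials and trial_duration must be positive")
  }
  if (floor(trial_duration * sampling_rate / 1000) < 1) {
    stop_config("trial_duration must contain at least one sample")
  }
  for (p in c(trackloss_rate, extreme_rate, aoi_inside_prob)) {
    if (p < 0 || p > 1) stop_config("rates and probabilities must lie in [0, 1]")
  }
  if (blink_rate < 0) stop_config("blink_rate must be >= 0")
  if (length(blink_duration) != 2 || blink_duration[1] > blink_duration[2]) {
    stop_config("blink_duration must be an increasing length-2 range")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    sampling_rate = sampling_rate,
    n_blocks = 2L,
    n_trials = as.integer(n_trials),
    trial_duration = trial_duration,
    tonic_mean = tonic_mean,
    tonic_sd_between = tonic_sd_between,
    noise_sd = noise_sd,
    blink_rate = blink_rate,
    blink_duration = blink_duration,
    trackloss_rate = trackloss_rate,
    extreme_rate = extreme_rate,
    aoi_inside_prob = aoi_inside_prob,
    high_missing_ids = as.integer(high_missing_ids),
    seed = as.integer(seed)
  ), class = "session_config")
}

#' Ground-truth condition effect for the generator
#'
#' The latent Visual minus Audiovisual difference at trial time t is
#' `beta_true + diff_curve(t)`: `beta_true` carries the mean effect over the
#' trial window and `diff_curve` is a zero-mean shape describing when the
#' effect unfolds. `participant_curve_sd` sets the amplitude of smooth
#' per-participant random time curves (a low-order random polynomial shared
#' by both blocks).
#'
#' @param beta_true mean Visual - Audiovisual offset, mm.
#' @param diff_curve vectorized function of trial time (ms) returning mm;
#'   must integrate to ~0 over the trial window.
#' @param participant_curve_sd SD of the per-participant random curve
#'   coefficients, mm.
#' @return A `true_effect` list.
#' @export
true_effect <- function(beta_true = 0,
                        diff_curve = function(t) rep(0, length(t)),
                        participant_curve_sd = 0.1) {
  stopifnot(is.function(diff_curve), participant_curve_sd >= 0)
  structure(list(
    beta_true = beta_true,
    diff_curve = diff_curve,
    participant_curve_sd = participant_curve_sd
  ), class = "true_effect")
}

#' Early-increase / late-decrease condition effect
#'
#' Canonical ground-truth shape: the Visual block shows no difference during
#' the first `onset` ms (the pupil's cognitive response latency, which also
#' keeps every baseline window effect-free), then a sinusoidal
#' early-positive / late-negative excursion of amplitude `amplitude` riding
#' on a plateau sized so that the mean difference over the whole trial
#' window equals `beta`.
#'
#' @param beta mean Visual - Audiovisual difference over the trial, mm.
#' @param amplitude amplitude of the early/late excursion, mm.
#' @param onset response latency in ms (no effect before this time).
#' @param trial_duration trial length in ms.
#' @return A `true_effect` object.
#' @export
effect_early_late <- function(beta = 0.1, amplitude = 0.2, onset = 200,
                              trial_duration = 1000) {
  stopifnot(onset >= 0, onset < trial_duration)
  plateau <- beta * trial_duration / (trial_duration - onset)
  g <- function(t) {
    out <- numeric(length(t))
    late <- t >= onset
    out[late] <- plateau +
      amplitude * sin(2 * pi * (t[late] - onset) / (trial_duration - onset))
    out
  }
  true_effect(
    beta_true = beta,
    diff_curve = function(t) g(t) - beta,
    participant_curve_sd = 0.1
  )
}

#' Null condition effect
#'
#' No mean difference and no time-varying difference between blocks;
#' per-participant random curves are retained so that the data keep
#' realistic (condition-unrelated) time structure.
#'
#' @param participant_curve_sd amplitude of per-participant random curves, mm.
#' @return A `true_effect` object.
#' @export
null_effect <- function(participant_curve_sd = 0.1) {
  true_effect(0, function(t) rep(0, length(t)), participant_curve_sd)
}

#' Ground-truth condition difference at a trial time
#'
#' Oracle for parameter-recovery tests: the latent Visual - Audiovisual
#' difference `beta_true + diff_curve(t)` at trial time `t`.
#'
#' @param effect a [true_effect()] object.
#' @param t trial times in ms, within `[0, trial_duration]`.
#' @param trial_duration trial length in ms.
#' @return numeric vector, mm.
#' @export
true_difference <- function(effect, t, trial_duration = 1000) {
  if (any(t < 0 | t > trial_duration)) {
    stop_domain("t outside the trial window [0, trial_duration]")
  }
  effect$beta_true + effect$diff_curve(t)
}

sample_times <- function(config) {
  n <- floor(config$trial_duration * config$sampling_rate / 1000)
  (seq_len(n) - 1) * 1000 / config$sampling_rate
}

empty_sample_table <- function() {
  tibble::tibble(
    participant_id = integer(0), block = character(0), trial = integer(0),
    t_trial = numeric(0), pupil_left = numeric(0), pupil_right = numeric(0),
    gaze_x = numeric(0), gaze_y = numeric(0), pupil_true = numeric(0),
    is_blink = logical(0), is_trackloss = logical(0), is_extreme = logical(0)
  )
}

#' Generate a clean synthetic session
#'
#' Produces one row per (participant, block, trial, sample) with the latent
#' pupil signal, noisy left/right observations, and gaze coordinates; no
#' artifacts are injected (all ground-truth flags are FALSE). The latent
#' signal is participant tonic level + condition effect (visual block only)
#' + per-participant smooth random curve; both eyes observe the latent
#' signal plus shared and eye-specific noise. Use [inject_artifacts()] (or
#' [simulate_session()]) to add blinks, trackloss and extreme values.
#'
#' @param config a [session_config()].
#' @param effect a [true_effect()].
#' @param geom a [screen_geometry()] used to place gaze points.
#' @return A tibble sample table with ground-truth columns.
#' @export
generate_session <- function(config, effect = true_effect(),
                             geom = screen_geometry()) {
  stopifnot(inherits(config, "session_config"), inherits(effect, "true_effect"))
  set.seed(config$seed)
  if (config$n_participants == 0) return(empty_sample_table())

  ts <- sample_times(config)
  ns <- length(ts)
  blocks <- c("audiovisual", "visual")
  base <- tidyr::expand_grid(
    participant_id = seq_len(config$n_participants),
    block = blocks,
    trial = seq_len(config$n_trials)
  )
  tab <- tidyr::expand_grid(base, t_trial = ts)

  tonic <- rnorm(config$n_participants, config$tonic_mean, config$tonic_sd_between)
  # per-participant random curve: a + b*P1 + c*P2 on scaled trial time,
  # zero-mean over the window (Legendre-type terms)
  pc_b <- rnorm(config$n_participants, 0, effect$participant_curve_sd)
  pc_c <- rnorm(config$n_participants, 0, effect$participant_curve_sd)
  x01 <- 2 * tab$t_trial / config$trial_duration - 1
  pcurve <- pc_b[tab$participant_id] * x01 +
    pc_c[tab$participant_id] * (3 * x01^2 - 1) / 2

  cond <- ifelse(tab$block == "visual",
                 effect$beta_true + effect$diff_curve(tab$t_trial), 0)
  latent <- tonic[tab$participant_id] + cond + pcurve

  n <- nrow(tab)
  shared <- rnorm(n, 0, config$noise_sd * sqrt(0.9))
  eye_sd <- config$noise_sd * sqrt(0.1)
  tab$pupil_left <- latent + shared + rnorm(n, 0, eye_sd)
  tab$pupil_right <- latent + shared + rnorm(n, 0, eye_sd)
  tab$pupil_true <- latent

  gz <- draw_gaze(tab, config, geom)
  tab$gaze_x <- gz$x
  tab$gaze_y <- gz$y
  tab$is_blink <- FALSE
  tab$is_trackloss <- FALSE
  tab$is_extreme <- FALSE
  tab[c("participant_id", "block", "trial", "t_trial", "pupil_left",
        "pupil_right", "gaze_x", "gaze_y", "pupil_true", "is_blink",
        "is_trackloss", "is_extreme")]
}

# Gaze is drawn in fixation-length dwells (400-800 ms) so that AoI filtering
# produces contiguous missing runs, as in real recordings. Inside dwells are
# uniform over the AoI rectangle; outside dwells uniform over the remaining
# screen (rejection sampling).
draw_gaze <- function(tab, config, geom) {
  n <- nrow(tab)
  x <- numeric(n)
  y <- numeric(n)
  dt <- 1000 / config$sampling_rate
  key <- paste(tab$participant_id, tab$block)
  for (k in unique(key)) {
    idx <- which(key == k)
    m <- length(idx)
    pos <- 1L
    while (pos <= m) {
      dwell <- max(1L, round(runif(1, 400, 800) / dt))
      seg <- idx[pos:min(m, pos + dwell - 1L)]
      inside <- runif(1) < config$aoi_inside_prob
      if (inside) {
        px <- runif(1, geom$aoi_left, geom$aoi_right)
        py <- runif(1, geom$aoi_top, geom$aoi_bottom)
      } else {
        repeat {
          px <- runif(1, 0, geom$width)
          py <- runif(1, 0, geom$height)
          if (px < geom$aoi_left || px > geom$aoi_right ||
              py < geom$aoi_top || py > geom$aoi_bottom) break
        }
      }
      jx <- pmin(pmax(px + rnorm(length(seg), 0, 5), 0), geom$width)
      jy <- pmin(pmax(py + rnorm(length(seg), 0, 5), 0), geom$height)
      # fixation jitter stays on the dwell's side of the AoI border, so the
      # gaze filter removes contiguous dwells, not flickering single samples
      if (inside) {
        jx <- pmin(pmax(jx, geom$aoi_left), geom$aoi_right)
        jy <- pmin(pmax(jy, geom$aoi_top), geom$aoi_bottom)
      } else {
        crossed <- jx >= geom$aoi_left & jx <= geom$aoi_right &
          jy >= geom$aoi_top & jy <= geom$aoi_bottom
        jx[crossed] <- px
        jy[crossed] <- py
      }
      x[seg] <- jx
      y[seg] <- jy
      pos <- pos + dwell
    }
  }
  list(x = x, y = y)
}

#' Inject blinks, trackloss and extreme values into a session
#'
#' Blinks are short binocular missing runs (Poisson starts at `blink_rate`
#' per second, duration uniform in `blink_duration`). Trackloss runs are
#' longer (500-1500 ms) and may affect one eye only. Extreme values replace
#' observed samples with values outside the 2-8 mm band, preferentially at
#' the band. Participants listed in `high_missing_ids` receive extra
#' binocular trackloss until more than 30% of their samples are missing.
#' Gaze is set missing wherever both eyes are missing. Ground-truth flag
#' columns are updated.
#'
#' Randomness continues the ambient RNG stream; use [simulate_session()] for
#' a fully seeded generate + inject run.
#'
#' @param table a sample table from [generate_session()].
#' @param config the [session_config()] that produced it.
#' @return The table with artifacts injected.
#' @export
inject_artifacts <- function(table, config) {
  stopifnot(inherits(config, "session_config"))
  if (nrow(table) == 0) return(table)
  for (p in c(config$trackloss_rate, config$extreme_rate)) {
    if (p < 0 || p > 1) stop_config("rates must lie in [0, 1]")
  }

  dt <- 1000 / config$sampling_rate
  tab <- dplyr::arrange(table, participant_id, block, trial, t_trial)
  tab$..bt <- (tab$trial - 1) * config$trial_duration + tab$t_trial
  key <- paste(tab$participant_id, tab$block)
  block_len <- config$n_trials * config$trial_duration

  for (k in unique(key)) {
    idx <- which(key == k)
    bt <- tab$..bt[idx]
    # blinks: both eyes
    if (config$blink_rate > 0) {
      nb <- rpois(1, config$blink_rate * block_len / 1000)
      if (nb > 0) {
        for (j in seq_len(nb)) {
          dur <- runif(1, config$blink_duration[1], config$blink_duration[2])
          start <- runif(1, 0, max(0, block_len - dur))
          hit <- idx[bt >= start & bt < start + dur]
          if (length(hit)) {
            tab$pupil_left[hit] <- NA_real_
            tab$pupil_right[hit] <- NA_real_
            tab$is_blink[hit] <- TRUE
          }
        }
      }
    }
    # trackloss: longer runs, possibly monocular, truncated to hit the target
    if (config$trackloss_rate > 0) {
      target <- round(config$trackloss_rate * length(idx))
      marked <- 0L
      guard <- 0L
      while (marked < target && guard < 200L) {
        guard <- guard + 1L
        dur <- runif(1, 500, 1500)
        start <- runif(1, 0, max(0, block_len - dur))
        hit <- idx[bt >= start & bt < start + dur]
        hit <- hit[!(is.na(tab$pupil_left[hit]) & is.na(tab$pupil_right[hit]))]
        if (!length(hit)) next
        hit <- hit[seq_len(min(length(hit), target - marked))]
        eye <- sample(c("both", "left", "right"), 1, prob = c(0.5, 0.25, 0.25))
        if (eye %in% c("both", "left")) tab$pupil_left[hit] <- NA_real_
        if (eye %in% c("both", "right")) tab$pupil_right[hit] <- NA_real_
        tab$is_trackloss[hit] <- TRUE
        marked <- marked + length(hit)
      }
    }
  }

  # extreme values: scattered among observed samples
  if (config$extreme_rate > 0) {
    observed <- which(!is.na(tab$pupil_left) & !is.na(tab$pupil_right))
    n_ext <- round(config$extreme_rate * length(observed))
    pick <- if (n_ext > 0) sample(observed, min(n_ext, length(observed)))
            else integer(0)
    if (length(pick)) {
      # blink-edge artifacts mostly shrink the apparent pupil (partial lid
      # occlusion), occasionally inflate it; values stay near the 2-8 mm
      # bounds ("extreme yet plausible")
      lowside <- runif(length(pick)) < 0.8
      val <- ifelse(lowside, runif(length(pick), 1.0, 1.95),
                    runif(length(pick), 8.05, 9.0))
      tab$pupil_left[pick] <- val
      tab$pupil_right[pick] <- val + rnorm(length(pick), 0, 0.02)
      tab$is_extreme[pick] <- TRUE
    }
  }

  # force listed participants above 30% missingness (binocular basis)
  for (pid in config$high_missing_ids) {
    rows <- which(tab$participant_id == pid)
    if (!length(rows)) next
    guard <- 0L
    repeat {
      miss <- mean(is.na(tab$pupil_left[rows]) | is.na(tab$pupil_right[rows]))
      if (miss > 0.32 || guard > 400L) break
      guard <- guard + 1L
      blk <- sample(c("audiovisual", "visual"), 1)
      rb <- rows[tab$block[rows] == blk]
      dur <- runif(1, 500, 1500)
      start <- runif(1, 0, max(0, block_len - dur))
      hit <- rb[tab$..bt[rb] >= start & tab$..bt[rb] < start + dur]
      if (length(hit)) {
        tab$pupil_left[hit] <- NA_real_
        tab$pupil_right[hit] <- NA_real_
        tab$is_trackloss[hit] <- TRUE
      }
    }
  }

  both_na <- is.na(tab$pupil_left) & is.na(tab$pupil_right)
  tab$gaze_x[both_na] <- NA_real_
  tab$gaze_y[both_na] <- NA_real_
  tab$..bt <- NULL
  tab
}

#' Generate a full synthetic session (signal + artifacts)
#'
#' Seeded wrapper: [generate_session()] followed by [inject_artifacts()],
#' all randomness flowing from `config$seed`.
#'
#' @inheritParams generate_session
#' @return A tibble sample table.
#' @export
simulate_session <- function(config, effect = true_effect(),
                             geom = screen_geometry()) {
  tab <- generate_session(config, effect, geom)
  inject_artifacts(tab, config)
}
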
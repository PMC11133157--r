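test_that("eye averaging takes the mean and defers monocular samples", {
  tab <- toy_series(c(4, 4, 4))
  tab$pupil_left <- c(4.0, 4.0, NA)
  tab$pupil_right <- c(4.2, NA, NA)
  tab$gaze_x <- tab$gaze_y <- 100
  out <- average_eyes(tab)
  expect_equal(out$pupil, c(4.1, NA, NA))
})

test_that("extreme filter uses strict 2/8 mm bounds and is idempotent", {
  s <- toy_series(c(4.1, 8.5, 1.2, 2.0, 8.0, 2.0001, 7.9999))
  f1 <- filter_extreme(s)
  expect_equal(is.na(f1$pupil),
               c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(attr(f1, "n_extreme_removed"), 4L)
  f2 <- filter_extreme(f1)
  expect_identical(f1$pupil, f2$pupil)
  expect_error(filter_extreme(s, low = 8, high = 2), class = "pv_config_error")
})

test_that("AoI membership is a closed rectangle and filtering is idempotent", {
  geom <- screen_geometry()
  s <- toy_series(rep(4, 5))
  s$gaze_x <- c((geom$aoi_left + geom$aoi_right) / 2,  # center
                0,                                     # screen corner
                geom$aoi_left,                         # exactly on left edge
                geom$aoi_right,                        # exactly on right edge
                NA)                                    # gaze missing
  s$gaze_y <- c((geom$aoi_top + geom$aoi_bottom) / 2,
                0, geom$aoi_top, geom$aoi_bottom, NA)
  f1 <- filter_aoi(s, geom)
  expect_equal(is.na(f1$pupil), c(FALSE, TRUE, FALSE, FALSE, TRUE))
  f2 <- filter_aoi(f1, geom)
  expect_identical(f1$pupil, f2$pupil)
})

test_that("blink detection finds maximal missing runs and classifies by duration", {
  # fully observed -> no segments
  expect_identical(nrow(detect_blinks(toy_series(rep(4, 60)))), 0L)
  # one 6-sample (100 ms at 60 Hz) run -> one blink segment
  p <- rep(4, 60)
  p[10:15] <- NA
  segs <- detect_blinks(toy_series(p))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_samples, 6L)
  expect_identical(segs$type, "blink")
  expect_equal(segs$end - segs$start, 100)
  # a 2 s run with max_blink_ms = 500 -> trackloss
  p2 <- rep(4, 240)
  p2[60:179] <- NA
  segs2 <- detect_blinks(toy_series(p2, trial = rep(1:4, each = 60)),
                         max_blink_ms = 500)
  expect_identical(segs2$type, "trackloss")
  expect_identical(segs2$n_samples, 120L)
  # runs never span participants: same positions, two participants
  p3 <- rep(c(4, NA), c(50, 10))
  two <- dplyr::bind_rows(toy_series(p3, participant_id = 1L),
                          toy_series(rev(p3), participant_id = 2L))
  segs3 <- detect_blinks(two)
  expect_identical(nrow(segs3), 2L)
  expect_setequal(segs3$participant_id, c(1L, 2L))
})

test_that("gap exclusion drops exactly the missing rows", {
  p <- rep(4, 60)
  p[c(5, 10:14)] <- NA
  out <- handle_gaps(toy_series(p), "exclude")
  expect_identical(nrow(out), 54L)
  expect_false(any(is.na(out$pupil)))
})

test_that("linear interpolation is exact on linear signals and only fills interior gaps", {
  # gap inside a linear ramp: filled values continue the ramp exactly
  p <- c(4.0, NA, NA, 4.3)
  out <- handle_gaps(toy_series(p), "interpolate")
  expect_equal(out$pupil, c(4.0, 4.1, 4.2, 4.3))
  # observed values are never altered
  p2 <- seq(3, 5, length.out = 30)
  holes <- c(7:9, 20)
  p2na <- replace(p2, holes, NA)
  out2 <- handle_gaps(toy_series(p2na), "interpolate")
  expect_identical(out2$pupil[-holes + 0][match(out2$t_trial, out2$t_trial)][1],
                   out2$pupil[1])
  expect_equal(out2$pupil, p2)  # linear latent recovered exactly
  # leading/trailing gaps stay missing and are dropped
  p3 <- c(NA, NA, 4, 4.5, NA)
  out3 <- handle_gaps(toy_series(p3), "interpolate")
  expect_identical(nrow(out3), 2L)
  # never fills across a participant/block boundary
  a <- toy_series(c(4, 4, NA), participant_id = 1L)
  b <- toy_series(c(NA, 5, 5), participant_id = 2L)
  out4 <- handle_gaps(dplyr::bind_rows(a, b), "interpolate")
  expect_identical(nrow(out4), 4L)  # boundary-adjacent gaps dropped, not bridged
})

test_that("subtractive baseline centers each trial on its window median", {
  # constant trial -> all zeros
  out <- baseline_correct(toy_series(rep(4, 60)), 100, "subtractive")
  expect_equal(out$y, rep(0, 60))
  # ramp, 100 ms window: baseline = median of first 6 samples (t < 100)
  p <- 4 + 0.02 * (0:59)
  s <- toy_series(p)
  out2 <- baseline_correct(s, 100, "subtractive")
  expect_equal(out2$y, p - median(p[s$t_trial < 100]))
  # shift invariance
  out3 <- baseline_correct(dplyr::mutate(s, pupil = pupil + 0.7), 100)
  expect_equal(out3$y, out2$y)
  # 16 ms window at 60 Hz contains exactly the first sample
  out4 <- baseline_correct(s, 16)
  expect_equal(out4$y, p - p[1])
  # trials with no observed window sample are dropped
  p5 <- rep(4, 120)
  p5[61:72] <- NA  # second trial loses its whole 200 ms window
  s5 <- toy_series(p5, trial = rep(1:2, each = 60))
  s5 <- s5[!is.na(s5$pupil), ]
  out5 <- baseline_correct(s5, 200)
  expect_identical(sort(unique(out5$trial)), 1L)
  expect_identical(attr(out5, "n_trials_dropped_baseline"), 1L)
  # divisive variant
  out6 <- baseline_correct(s, 100, "divisive")
  expect_equal(out6$y, p / median(p[s$t_trial < 100]))
})

test_that("participant missingness uses the strict 30% rule", {
  full <- toy_series(rep(4, 60))
  expect_identical(participant_missingness(full)$missing_frac, 0)
  # 540 of 1080 missing -> 0.5, flagged
  p <- rep(c(4, NA), each = 540)
  s <- toy_series(p, trial = rep(1:18, each = 60))
  m <- participant_missingness(s)
  expect_equal(m$missing_frac, 0.5)
  expect_true(m$flagged)
  # exactly 30% -> not flagged (strict >)
  p2 <- c(rep(NA, 30), rep(4, 70))
  m2 <- participant_missingness(toy_series(p2, trial = rep(1:2, each = 50)))
  expect_equal(m2$missing_frac, 0.3)
  expect_false(m2$flagged)
})

test_that("fork lattice has the printed combinatorial structure", {
  g <- fork_grid()
  expect_identical(nrow(g), 48L)
  expect_identical(anyDuplicated(g$fork_token), 0L)
  # serialization round-trips
  for (i in seq_len(nrow(g))) {
    fk <- parse_fork_token(g$fork_token[i])
    expect_identical(fork_token(fk), g$fork_token[i])
  }
  expect_identical(fork_token(fork_spec("trimmed", "aoi_only", "interpolate",
                                        100, "exclude_high_missing")),
                   "trimmed|aoi|interp|100|excl")
})

test_that("the lattice grows 4 -> 8 -> 24 -> 48 along the forking steps", {
  tab <- tiny_session(seed = 21, n_participants = 3)
  expect_length(build_multiverse(tab, steps = 2), 4L)
  expect_length(build_multiverse(tab, steps = 3), 8L)
  expect_length(build_multiverse(tab, steps = 4), 24L)
  mv <- build_multiverse(tab, steps = 5)
  expect_length(mv, 48L)
  toks <- vapply(mv, function(d) fork_token(d$fork), character(1))
  expect_identical(sort(toks), sort(fork_grid()$fork_token))
})

test_that("processed datasets never gain rows and the laxest fork keeps the most", {
  tab <- tiny_session(seed = 22, n_participants = 3)
  mv <- build_multiverse(tab)
  toks <- vapply(mv, function(d) fork_token(d$fork), character(1))
  rows <- vapply(mv, function(d) nrow(d$data), integer(1))
  expect_true(all(rows <= nrow(tab)))
  laxest <- rows[toks == "all|screen|interp|16|incl"]
  expect_identical(max(rows), laxest)
  for (d in mv) {
    expect_false(any(is.na(d$data$y)))
    # every retained (participant, block, trial) has >= 1 sample by construction
    expect_true(all(table(paste(d$data$participant_id, d$data$block,
                                d$data$trial)) >= 1))
  }
})
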
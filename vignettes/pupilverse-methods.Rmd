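---
title: "Methods: a preprocessing and modelling multiverse for infant pupillometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a preprocessing and modelling multiverse for infant pupillometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Event-locked pupillometry in infants produces long per-sample time series
(here: binocular 60 Hz recordings of two familiarization blocks, audiovisual
and visual, each nine consecutive 1-s trials) that must be heavily
preprocessed before any model sees them. Each preprocessing step involves an
arbitrary-but-plausible choice, and those choices can drive the substantive
conclusion. `pupilverse` treats the choices explicitly as a multiverse: every
combination of

1. extreme-value handling: keep all values, or trim to the physiological
   2-8 mm band (strict inequalities: exactly 2 or 8 mm is removed),
2. gaze filtering: whole screen, or only samples inside a central area of
   interest (closed rectangle: edge points are kept),
3. gap handling: drop missing samples, or linearly interpolate interior
   gaps within a participant x block,
4. baseline correction window: 16, 100, or 200 ms (per-trial subtractive
   correction against the window median),
5. participant inclusion: keep everyone, or drop participants with more
   than 30% missing samples (strict inequality, measured after the filters
   and before gap handling),

is one dataset: 2 x 2 x 2 x 3 x 2 = 48 datasets from one recording. Two
competing regression models are fitted to each, giving a 96-estimate
specification curve of the Visual - Audiovisual block effect.

The operators run in the order listed; baseline correction runs after gap
handling and participant exclusion last. Eye averaging precedes everything:
the monocular series is the mean of the two eyes where both are observed,
and missing otherwise, so monocular samples are resolved by the gap fork.
The multiverse uses subtractive baselines only; a divisive variant
(`y = pupil / baseline`) is exposed off-lattice because it is occasionally
requested, with non-positive baselines dropping the trial.

## The two models

Both models regress the baseline-corrected pupil change `y` on the
familiarization block, per sample:

* **time model**: `y = alpha + beta * visual + f_block(t) + f_id(t) + e`,
  where `f_block` is a separate penalized cubic B-spline of trial time per
  block level (k = 20 basis functions by default) and `f_id` is a
  factor-smooth term per participant;
* **no-time model**: `y = alpha + beta * visual + c_(id, block) + e`, with
  one ridge-penalized coefficient per participant x block cell.

`beta` is the mean Visual - Audiovisual difference; the specification curve
plots its 96 estimates. Models are compared within each dataset by
`BIC = -2 loglik + (edf + 1) log n` - penalized models have no integer
parameter count, so the effective degrees of freedom (trace of the hat
matrix) stands in, plus one for the residual scale - and by adjusted
`R^2 = 1 - (RSS / (n - edf)) / (TSS / (n - 1))`. Delta-BIC evidence bands:
below 2 weak, 2-6 positive, 6-10 strong, above 10 very strong.

### Identifiability and the factor-smooth decomposition

Each condition smooth is constrained to zero mean over its own block's
rows, so the block contrast lives entirely in `beta`. The participant terms
required more care. A naive per-participant spline with a single shared
smoothing parameter fails twice in practice. First, if the term is
sum-to-zero constrained, it cannot represent the per-participant *level*
that baseline-corrected data genuinely retain (the random time curve's
value inside the baseline window is subtracted from the whole trial,
leaving a participant-constant offset), and the no-time model's cells then
beat the time model on likelihood for reasons that have nothing to do with
time. Second, when the smoothing parameter is selected near zero, an
unconstrained participant spline on unbalanced (gappy) data can leak into
`beta`: in one pilot the true +0.10 mm effect was estimated as -0.13 mm.

The final structure therefore decomposes each participant term as a
ridge-penalized participant intercept plus a spline deviation constrained
to zero mean *within each of that participant's blocks*. The deviation can
never shift block means, so `beta` remains the mean contrast at any
smoothing level; the intercept carries the level. Wiggliness (a
second-order difference penalty built from divided differences over the
Greville abscissae, so its null space is exactly the straight lines) and
the level/null-space ridge get separate smoothing parameters, shared
across participants - the usual factor-smooth arrangement, for the usual
reason: random-curve amplitude and random-level amplitude are different
variance scales, and forcing them through one parameter either overfits
every participant curve or deletes real structure.

### Smoothing-parameter selection

Smoothing parameters minimize the GCV score `n RSS / (n - gamma * edf)^2`
over a log-spaced grid (`10^-4` to `10^6`, 11 points) by coordinate
descent: one grid pass per parameter per sweep, stopping when the score
changes by less than 1e-6 relative or after 25 sweeps. The inflation
`gamma = 1.4` (the customary guard in additive modelling) is the default
because the residuals are not independent - see next section - and plain
GCV undersmooths under dependent noise. All penalties are evaluated on
trial time rescaled to the unit interval and are normalized to unit mean
diagonal, so one lambda grid serves every term.

With every penalty forced to zero the solver reproduces ordinary least
squares to machine precision on full-rank designs; this, and a brute-force
Cox-de Boor recursion for the basis, are the oracles in the test suite.
`mgcv` fits the analogous model in one test as an independent cross-check
of the estimated condition-difference curve; it is never the
implementation.

### Why the block effect's CI is cluster-robust

Per-trial subtractive baselining subtracts a window median - a noisy
quantity - from all ~60 samples of the trial, so every trial's residuals
share a common shift and the iid model-based standard error of `beta`
understates its sampling variability by roughly a factor of three
(predicted coverage of a nominal 95% interval: ~40-60%). `beta`'s SE and
CI therefore use a trial-clustered sandwich covariance (CR1 small-sample
factor, normal quantile). In 60-session pilot studies the clustered SE
(0.014) matched the empirical sampling SD (0.015) and the 95% CI covered
the truth in ~92% of replications. The model-based covariance
`sigma^2 (X'X + sum lambda_j S_j)^{-1}` is kept for the smooth confidence
bands (standard additive-model practice) and is exposed as `coef_cov`;
its bands inherit the same caveat and should be read as approximate.

The condition-difference smooth is
`beta + f_visual(t) - f_audiovisual(t)` on a 101-point grid, with
pointwise Wald bands and significant windows reported as maximal
contiguous runs of grid points whose band excludes zero.

## The synthetic-session generator

The generator exists so that every stage is testable with known ground
truth. One seed drives everything. The latent signal per sample is
participant tonic level (mean 4.0 mm, between-participant SD 0.4 mm) +
condition effect (visual block only) + a per-participant random quadratic
time curve (Legendre terms, coefficient SD 0.1 mm); both eyes observe it
through shared (90% of variance) plus eye-specific (10%) white noise of
total SD 0.15 mm, which keeps the left/right correlation near the
physiological ~0.96. The canonical condition effect is zero during a
200 ms response latency - which also keeps every baseline window
effect-free, so the pipeline's `beta` estimand equals the generator's
`beta_true` - then an early-positive/late-negative sinusoidal excursion
riding on a plateau sized so the whole-trial mean equals `beta_true`.

Artifacts: blinks are binocular missing runs (Poisson starts at 0.3/s,
100-400 ms); trackloss runs are longer (500-1500 ms), possibly monocular,
targeted at 8% of samples; extreme values replace ~1% of scattered
observed samples with values just outside the 2-8 mm band, 80% low-side
(partial lid occlusion shrinks the apparent pupil). Gaze is drawn in
fixation-length dwells (400-800 ms, 90% inside the AoI, jitter clamped to
the dwell's side of the AoI border), so AoI filtering removes contiguous
runs rather than salt-and-pepper samples. The blink classifier imposes a
physiological minimum duration (50 ms by default): sub-blink missing runs
- single-sample dropouts, including trimmed extreme values - are reported
as dropouts, not blinks, which keeps the blink diagnostics aligned with
the pattern that datasets retaining extreme values show the most blinks. Listed
participants receive extra binocular trackloss until they exceed 30%
missingness.

What the generator does *not* emulate: saccade/fixation dynamics beyond
dwell lengths, luminance-driven pupil responses, autocorrelated
measurement noise, drift in tonic level across the session, or vendor
validity-flag semantics. Passing tests therefore certify the pipeline's
logic and the estimator's calibration under this generative model, not
performance on any particular tracker's raw output.

The default AoI geometry derives from the apparatus: a 10 x 10 degree
stimulus at 60 cm on a 109-ppi screen is ~450 px, plus a 1 cm ~ 43 px
margin, centered on a 2560 x 1440 screen; all of it is overridable.

## Numerical and policy choices

* Basis: clamped equally-spaced knots (so k = 4 recovers the Bernstein
  basis and the rows sum to one); evaluation by `splines::splineDesign`.
* Degenerate forks (no rows, one block, or fewer than two participants
  after exclusion) stay in the lattice flagged degenerate; fit errors are
  recorded per fork and never abort the run.
* Participants with fewer than 10 rows in a dataset are dropped from that
  fit with a warning.
* Trials with no observed sample in the baseline window are dropped with a
  provenance record.
* The specification curve sorts ascending by estimate, ties broken by fork
  token; significance for coloring is the 95% CI excluding zero.
* CSV dialect: comma, decimal point, UTF-8, missing = empty field; reading
  uses base R's correctly-rounded float parser so write-read-write is
  byte-identical.

## Validation-study problem sizes

The packaged studies use sizes chosen to exercise the full pipeline while
staying desk-scale: the lattice and model-selection study runs one
8-participant session (two participants forced high-missing, mirroring the
4-of-16 pattern in the motivating study) with a clearly detectable effect
(`beta = 0.1` mm, excursion amplitude 0.3 mm); parameter recovery runs 100
seeded 6-participant sessions; null calibration runs ten 6-participant
null sessions with k = 10 (the block coefficient's calibration does not
depend on basis size). Because all 96 estimates within one session share a
noise realization, the null study's significance fraction is compared with
its nominal level using the between-seed standard error rather than a
pooled binomial one.

## Known limitations

* BIC model selection is honest but fragile in the all-values x 16-ms
  cell of the lattice: a single extreme value landing on a one-sample
  baseline shifts an entire trial by several millimetres, structure the
  no-time model's participant-by-block cells can absorb but the time
  model (whose participant terms are block-constant) cannot. Short
  baselines being susceptible to recording noise is a known property of
  subtractive correction; the multiverse makes it visible rather than
  hiding it.
* Residual autocorrelation beyond the trial-level clustering (e.g. AR
  noise within trials) is not modelled; the smooth confidence bands are
  approximate under it.
* GCV selection over a finite grid can sit at the grid boundary for
  near-unpenalized terms; widen `lambda_grid` if that matters for an
  application.
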
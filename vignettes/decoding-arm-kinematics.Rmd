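---
title: "Decoding arm kinematics from EMG envelopes with pair-selected Kalman filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding arm kinematics from EMG envelopes with pair-selected Kalman filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgkalman)
```

## The decoding problem

Surface EMG recorded over the biceps, triceps, anterior deltoid and lateral
deltoid carries enough information about planar arm movement to drive a
prosthesis continuously: rather than classifying discrete gestures, the
decoder estimates, every 100 ms, the interior elbow angle θ and the wrist
position (X, Y). `emgkalman` implements this as linear-Gaussian state-space
filtering. The state `r` is a subset of (θ, X, Y); the measurement `z` is
the vector of EMG linear envelopes:

$$r_{n+1} = A\,r_n + w_n, \qquad z_n = H\,r_n + q_n,$$

with `w ~ N(0, W)`, `q ~ N(0, Q)` and all four matrices assumed
time-invariant so they can be identified from a training session.

### Identification

`fit_kalman_model()` estimates `A` and `H` by least squares on the windowed
training data — `A = R2 R1'(R1 R1')⁻¹`, `H = Z R'(R R')⁻¹` — and the noise
covariances as residual second moments, `W` scaled by the number of
transition pairs and `Q` by the number of windows. Two numerical guards
matter in practice:

* **Pseudo-inverse fallback.** Rest periods leave kinematic channels nearly
  constant, so the Gram matrices `R1 R1'` and `R R'` can be rank-deficient.
  When the reciprocal condition number drops below 1e-12 the solver
  switches to a Moore–Penrose pseudo-inverse and emits a conditioning
  warning rather than failing or silently amplifying noise.
* **PSD repair.** `W` and `Q` are PSD analytically, but floating-point
  asymmetry is enough to break the innovation solve downstream. Both are
  symmetrized and eigenvalue-floored at 1e-12.

When training data consist of several disjoint segments (a validation block
cut out of a session, or several subjects pooled), `R`/`Z` concatenate all
segments but the transition pairs `R1`/`R2` are formed within segments
only, so no transition is fabricated across a gap.

### Filtering

`decode_sequence()` runs the textbook recursion — time update
`r⁻ = A r`, `P⁻ = A P A' + W`; measurement update with gain
`K = P⁻H'(H P⁻ H' + Q)⁻¹`. The innovation covariance is solved as a
symmetric system (never explicitly inverted), giving bit-stable output for
fixed input. The recursion starts from an all-ones state and an identity
covariance: "one" for a matrix is read as unit diagonal, since an all-ones
covariance would be singular. Decoding a stream in chunks while carrying
the `final_state` attribute is exactly equivalent to one batch call. No
smoothing, square-root filtering or adaptive noise re-estimation is
performed; the plain covariance form matches the model being studied, with
post-hoc symmetrization for hygiene. EMG and kinematics are aligned at lag
zero; electromechanical delay is not modeled.

## The multi-filter scheme

A single filter can carry all three parameters (d = 3), or each parameter
can get its own scalar filter. The package's headline decoder instead fits
the three **pair** filters (θ,X), (θ,Y), (X,Y) and, per parameter, keeps
the pair that decodes it best:

1. `select_combinations()` cuts a contiguous validation block covering 20%
   of each training segment at a seeded random offset. Contiguity is
   deliberate: EMG envelopes and kinematics are strongly autocorrelated, so
   scattered validation windows would leak training information into the
   score. With a single training session this is exactly one contiguous
   block; with pooled segments one proportional block per segment is drawn,
   which degrades gracefully to the same design. The block is folded back
   into training before the final fit.
2. Each pair filter decodes the validation block; per parameter the pair
   with the higher validation CC wins, with ties broken by lower NRMSE and
   then canonical pair order — CC is the primary published performance
   measure, so it is also the selection metric. A constant validation
   parameter makes CC undefined; ranking falls back to NRMSE with a
   warning.
3. `fit_multi_decoder()` refits one model per distinct winning pair on the
   full training data. Three parameters and two slots per pair normally
   yield two filters; the argmax can name three distinct pairs, in which
   case all three are fitted and a warning notes the departure. We keep the
   faithful per-parameter argmax rather than forcing a two-pair cover.

## Performance measures

`pearson_cc()` (product-moment correlation), `rmse()`, and `nrmse()`
(RMSE divided by the *actual* signal's range, making errors comparable
across parameters). One sample count is used throughout a report. Constant
signals make CC and NRMSE undefined and raise classed errors; the
evaluation layer records `NA` for such folds instead of inventing a value.

## Preprocessing

The fixed pipeline is: optional digital filtering and RMS envelope
extraction (EMG only) → per-channel min–max normalization → amplitude
rescaling (EMG ×10³, kinematics ×10², the constants used to bring signals
to the acquisition device's working range) → non-overlapping 100-ms
windows, reduced by the mean. Choices the data description leaves open:

* **RMS window = 100 ms**, matching the decoder step so the envelope
  timescale equals the state timescale; configurable.
* **Window reduction = mean** (a `last` option exists for sensitivity
  checks).
* **Normalization scope.** Inside evaluation protocols the min/max
  constants are computed on training windows only and applied affinely to
  test windows, avoiding test-set leakage; test values may then fall
  slightly outside [0, 1]·scale, which the filter tolerates. Because
  normalization is affine and windows are means, normalizing before or
  after windowing is equivalent up to which extremes define the constants.
* **Digital filters off by default.** The 10 Hz high-pass / 500 Hz
  anti-alias stage belongs to acquisition hardware; software equivalents
  (Butterworth, via the `signal` package) exist for raw-signal inputs but
  synthetic sessions are generated at the envelope level.

## The synthetic cohort

Real recordings for this task are not redistributable, so the package
generates its own study: ten subjects, each with a 400 s and a 200 s
session of planar movements — elbow flexion/extension with or without
shoulder flexion/extension, interleaved with 2–3 s rests — at 100 Hz.

* **Kinematics.** Joint targets are drawn uniformly (interior elbow angle
  70–170°, 180° = full extension; shoulder elevation −20° to 90°) and
  connected by minimum-jerk profiles, the standard model for naturalistic
  reach velocity. Wrist position follows two-link forward kinematics
  `X = L1 cos φ + L2 cos(φ + θ')`, `Y = L1 sin φ + L2 sin(φ + θ')` with
  `θ' = 180° − θ` and links of 0.30/0.32 m. The forward-kinematic coupling
  makes θ and X co-vary (|CC| > 0.3 in every tested seed), the qualitative
  feature the pair-selection scheme exploits.
* **EMG envelopes** combine a tonic posture-holding term (elbow flexors
  load with flexion; deltoid activity scales with elevation above the
  resting hang) and a phasic rectified-velocity term, plus a baseline and
  Gaussian noise clipped at zero. Weights (tonic 1.0, phasic 0.35, noise
  sd 0.04) were calibrated once so that per-parameter decoding CC lands in
  roughly 0.65–0.88 — a nontrivial but solvable task near the
  subject-dependent range reported for real recordings — and then frozen.
* **Cohort spread.** Per-subject log-normal jitter (sd 0.15) of gains,
  link lengths and movement mix emulates anatomical and behavioral
  variability; two sessions per subject differ only by seed.

What the generator does **not** emulate: raw interference-pattern EMG (it
produces envelopes directly), electromechanical delay, fatigue or
electrode-shift nonstationarity, supination/pronation, and any
physiological muscle model. Passing tests therefore demonstrate the
correctness and internal consistency of the estimator/filter/selection
machinery under the stated assumptions — not decoding performance on real
surface EMG.

### A limitation the synthetic study exposes

On this generator the single full-state filter (d = 3) decodes slightly
*better* than the pair-selected decoder (by 0.01–0.07 CC, consistently
across seeds and coupling strengths). That is expected: for stationary
near-linear-Gaussian data with numerically guarded identification, the
3-state filter strictly generalizes every pair filter. Reports of the
full-state filter collapsing on real recordings are plausibly due to
ill-conditioned three-state identification (strongly collinear θ and X)
without pseudo-inverse protection, or to nonstationarity between training
and test — neither of which this generator reproduces. The package keeps
all three architectures so the comparison can be rerun on any data.

## Evaluation protocols

All protocols are pure functions of (cohort, configuration, seed) and
re-run bit-identically.

* **Subject-dependent:** per subject, a contiguous test block covering 25%
  of the windows at a seeded random offset, for each of 10 folds
  (`split = "session"` instead trains on session 1 and tests on session
  2). Contiguous blocks are used for the same anti-leakage reason as the
  validation block.
* **Leave-one-out:** the other nine subjects' windowed sessions are
  normalized per subject, concatenated as segments, and used to select and
  fit; the held-out subject's sessions are decoded and scored.
* **Donor transfer:** train on one subject (by default the best
  subject-dependent performer), decode everyone else.

Grand summaries are means of per-subject means — never a silent pooling of
folds. Problem sizes used throughout the test-suite and the acceptance
script (10 subjects, 400 s + 200 s at 100 Hz, 10 folds, 20 000-window
identification checks) keep a full run in a few minutes on one CPU.

## Degenerate inputs and numerical conventions

* Constant signals: min–max normalization, CC and NRMSE raise classed
  degenerate-range errors; callers decide the fallback.
* Empty measurement sequences decode to an empty matrix; a decoder whose
  filters do not cover all three parameters refuses to decode.
* Window binning applies a 1e-9 epsilon before `floor()` so samples on an
  exact window boundary are not shifted by floating-point division.
* Session files are CSV with a `#` metadata block, written with 15
  significant digits so a write/read round trip is lossless at double
  precision.
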
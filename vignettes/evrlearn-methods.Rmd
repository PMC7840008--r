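---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evrlearn)
```

# The task and its measurements

The paradigm is a repeated billiards shot performed in embodied virtual
reality: the player holds a physical cue and strikes a physical cue ball
on a physical table, while seeing the scene only through a headset whose
virtual objects are calibrated onto the real ones. Each session is 300
shots at a fixed corner-pocket target, analysed in 12 blocks of 25
trials. Two spaces are measured simultaneously:

- **task space** — the angle at which the target ball leaves, against
  the angle that would drop it in the pocket centre;
- **body space** — 51 joint angular-velocity channels (17 body segments
  × 3 Euler DoF) from an IMU suit at 60 Hz.

The package implements the full measurement chain for both spaces plus
the two data sources that make it testable end to end: a synthetic
cohort generator and a 2D shot-physics simulator.

# Task-space model

## Directional error and the angle convention

Bearing 0° points at the far cushion; positive angles are leftward. This
sign convention is the package's own (the underlying measurement only
needs absolute differences); it is documented here and used consistently
by the simulator, the generator, and the metrics. The trial error is the
absolute difference between the target ball's initial movement bearing
and the start→pocket bearing, wrapped to [0°, 180°].

## Robust intertrial variability

Block centre and spread come from a maximum-likelihood location–scale
t-distribution fit rather than mean/SD, so single wild shots do not
dominate a 25-trial block. The degrees of freedom are estimated, not
fixed, and bounded to [1, 100] for numerical stability; at the upper
bound the fit is effectively Gaussian, so the bound is not a material
constraint. Blocks with fewer than 5 trials fall back to median and
scaled MAD and are flagged. Zero-spread blocks return σ = 0 at the df
upper bound. Within `block_stats()` the centre μ is fitted on absolute
errors (the learning curve's quantity) and the ITV σ on signed
directions — a signed quantity is the only one on which the
learning-trend correction below is meaningful.

## Corrected ITV and a small-sample bias

Within a block, part of the spread is systematic within-block learning.
The corrected ITV fits an ordinary least-squares line to the signed
direction against within-block trial index and takes the robust t-fit
scale of the residuals. Two regression parameters are estimated from 25
points, so raw residuals underestimate the noise scale; the package
applies the standard df correction (residuals × √(n/(n−2))) before the
fit. Without it the recovered scale of a 2°-noise trending block
averages ≈1.80°; with it ≈1.87°. The remaining gap is the t-MLE's own
finite-sample shrinkage on near-Gaussian data and is left as is — it is
a property of the estimator, not an error.

# Body-space model

Each trial's 51-channel velocity matrix is cropped to a 1-s window
centred on the movement peak — the sample maximizing the mean absolute
velocity over the six right-shoulder and right-elbow channels. The
window is symmetric and inclusive (61 samples at 60 Hz); "1 second
around the peak" does not specify the discretisation, so ±0.5 s
inclusive is the package's documented choice. Trials whose peak sits
within half a window of a recording edge are rejected and flagged, never
padded: padding would inject artificial zero-velocity samples into every
covariance-based metric. No smoothing is applied before differentiation
by default (none is part of the method's definition); velocities are
central finite differences, which are exactly invariant to the constant
offsets and slow drift that IMU angle estimates accumulate — the reason
the analysis lives in velocity space at all.

From the window:

- **Generalized variance** is det(Σ) via eigendecomposition of the
  symmetrized covariance; tiny negative round-off determinants are
  clipped to 0.
- **PC spectrum** is the covariance eigenvalues normalized to fractions.
  Covariance, not correlation: all channels share deg/s units, and
  rescaling to correlation would erase exactly the amplitude structure
  the metrics are about.
- **DoF count** counts fractions strictly above 1%.
- **Manipulative complexity** is only anchored by its boundary
  behaviour (C = 1 equal spread, C = 0 degenerate spread). The package's
  default realization is the normalized participation ratio
  C = (PR − 1)/(N − 1), PR = 1/Σλ̂ᵢ²; a normalized-entropy variant
  ((e^H − 1)/(N − 1)) is available behind the `strategy` argument. Both
  meet the boundary conditions; the participation ratio is the default
  because it is the standard effective-dimensionality estimator and
  needs no convention for zero eigenvalues.
- **VPE** takes, per channel, the minimum correlation distance to that
  channel's profile in the session's successful trials. Successful
  trials are pooled over the whole session (a causal past-only variant
  would make early trials' VPE undefined). A successful trial compared
  against a library containing itself is trivially at distance 0, so
  `exclude_self` defaults to on; the literal pooled reading is one flag
  away. Zero-variance (flat) profiles have no defined correlation and
  are flagged NA, not imputed.

# Learning-curve fits

Metrics are fitted over trials (not blocks) with
y(t) = c + a·e^(−t/τ), and GV — which rises fast over the first ~30
trials then decays slowly — with the difference form
y(t) = c + a₁·e^(−t/τ₁) − a₂·e^(−t/τ₂), τ₂ < τ₁ enforced by
parameterization. The double-exponential's exact parameterization is a
package choice: the difference of exponentials is the simplest form with
the fast-rise/slow-decay shape and nests the single exponential at
a₂ = 0. Fitting uses variable projection (amplitudes solved linearly,
time constants optimized in log space) from a fixed multi-start grid
τ ∈ {5, 10, 20, 40, 80, 160} trials, which removes the local-minimum
sensitivity that plagues naive 4- or 5-parameter exponential fits. The
first-to-last-block delta uses a two-sided paired t-test (sidedness is a
package convention, not part of the method's definition).

# The shot-physics simulator

The strike is estimated from the cue-tip stream as the componentwise
median of the per-frame finite-difference velocities over the 10 frames
(~0.11 s at 90 Hz) before contact; the median of the velocity *vectors*
(not of speeds and angles separately) keeps speed and direction
mutually consistent and robust to one corrupted frame. Ball motion is
uniform frictional deceleration; contact uses a swept-circle test per
step so fast shots cannot tunnel through the target. The engine being
emulated hard-codes the ball–ball collision as "perfectly inelastic",
but a literally sticking collision cannot launch a separately travelling
target ball; the package therefore implements line-of-centres transfer
with a restitution parameter, default e = 1 (idealized equal-mass
billiards: the normal velocity component transfers entirely). Friction
magnitude, stop threshold, and ball masses are not published; they are
config defaults (0.6 m/s², 0.02 m/s, equal masses) and nothing
downstream depends on their exact values. Spin, follow-through, and
cushion rebounds are deliberately out of scope, matching the emulated
engine's own simplifications.

Frame calibration mirrors the shared-vertical-axis setup: a planar
similarity transform (closed-form complex least squares over landmark
correspondences — the study's five: four corner pockets plus the
cue-ball spot) plus a least-squares linear height ratio.

# The synthetic cohort: what it states and what it does not

The generator is the package's stated world, fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 10 | cohort size of the emulated study |
| `n_trials` / `block_size` | 300 / 25 | session length, 12 blocks |
| `error_asymptote` | 4° | late-session residual error |
| `error_amplitude_mean` / `_sd` | 10° / 3° | decaying error amplitude, between subjects |
| `error_decay_tau` | 100 trials | slow EVR learning |
| `motor_noise_sd` | 6° | per-trial directional noise |
| `success_tolerance` | 3° | pocket capture half-angle |
| `kinematics_rate` | 60 Hz | IMU suit rate |

The mean absolute-error curve is m(t) = c + A·e^(−(t−1)/τ) with A
truncated-normal per subject. Amplitude and τ are chosen so the expected
first-to-last block reduction is ≈8.3° with between-subject SD ≈2.5°,
the session improvement this task produces at this scale; the per-trial
noise SD and tolerance are *not* published quantities — they are package
defaults documented here. The signed direction is s·m(t) + ε with a
per-**subject** side s = ±1: a per-trial random sign would fold the
decaying mean curve into the signed-direction variance and manufacture
exactly the ITV decay the EVR condition must not show. The EVR preset
keeps the noise SD constant over trials (the paradigm's signature
finding); the `real_world` preset decays it (6° → 2.5°, τ = 80) and
speeds learning (τ = 30), giving the contrast the trend tests need.

Kinematics are Gaussian velocity bumps per channel (amplitude, peak
time 1.5 s, width 0.15 s) plus white noise, integrated to angles for
the on-disk CSV; shoulder amplitudes drift 120 → 70 deg/s and right
elbow rotation 20 → 60 deg/s with the learning time constant, the
full-body reorganisation signature. The bump parameterization is chosen
precisely because peak locations and block-wise variance changes are
then analytic, so tests have oracles. The generator does **not** emulate
a biomechanical skeleton, IMU drift (the velocity analysis is designed
to be immune to it), multi-phase movements, or trial-length variability
— so green tests establish that the pipeline recovers the structure the
generator states, not that it would denoise arbitrary real recordings.

# Numerical choices

- t-MLE via L-BFGS-B on (μ, log σ, log ν), three ν starts {2, 5, 30},
  best likelihood kept.
- Exponential fits: profiled linear parameters; 1-D `optimize` per
  τ start with tol 1e-12 (single), Nelder-Mead then BFGS polish on the
  ordered pair (double).
- Peak ties break to the first maximum (`which.max`).
- GV symmetry tolerance 1e-8 relative; spectra clipped at 0.
- Window length `round(rate) + 1` samples, peak-centred inclusive.
- Seeding: every generator takes an explicit seed and restores the
  caller's RNG state, so library use never clobbers a session's RNG.

# Known limitations

- Absolute GV magnitudes depend on the generator's amplitude scale and
  are not comparable to any recording-derived value.
- The t-fit scale on near-Gaussian 25-trial blocks retains a few percent
  downward shrinkage (see above).
- The simulator's outcome distribution is not calibrated to human
  shot-speed distributions; it is a mechanism twin, not a behaviour
  twin.
- The CLI is a thin orchestration layer; it does not validate config
  files beyond what the underlying functions check.
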
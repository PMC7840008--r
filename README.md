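# evrlearn

Analysis pipeline for short-term motor learning in a repeated
billiards-shot task performed in embodied virtual reality (EVR) — a VR
environment where the visible virtual table, balls and cue coincide with
physical objects the player touches. Subjects shoot 300 repeated shots at
a corner pocket while full-body kinematics are recorded from a 17-segment
IMU suit at 60 Hz (51 joint-angle channels: 3 Euler DoF per segment). The
package is aimed at motor-neuroscience researchers who want the task- and
body-space learning metrics of this paradigm as tested, reusable code,
plus synthetic data and a shot-physics simulator so every stage can be
exercised without motion-capture hardware.

## What it computes

**Task space** (per trial / per 25-trial block)

- Directional error: |angle between the target ball's initial movement
  and the direction from its start to the pocket centre|.
- Success rate: fraction of pocketed shots per block.
- Intertrial variability (ITV): the scale σ of a maximum-likelihood
  location–scale t-distribution fit to each block's shot directions
  (robust to outlier shots), and a *corrected* ITV — the same robust
  scale on the residuals of a within-block linear trend, removing
  learning that happens inside the block.

**Body space** (per trial, on a 1-s velocity window centred on the
movement peak of the right shoulder + elbow channels)

- Generalized variance GV = det(Σ), Σ the covariance of the 51 joint
  angular-velocity channels over the window.
- PCA dimensionality: the number of principal components explaining
  more than 1% of variance.
- Manipulative complexity: C = (PR − 1)/(N − 1) with participation
  ratio PR = 1/Σλ̂ᵢ²; C = 1 when all PCs contribute equally, C = 0 when
  one PC carries everything.
- Velocity profile error (VPE): per channel, min over successful trials
  of (1 − Pearson r) between velocity profiles — distance to the nearest
  successful movement solution.

**Learning dynamics**: least-squares fits of y(t) = c + a·e^(−t/τ)
(and a double-exponential fast-rise/slow-decay variant for GV), and the
paired first-to-last-block learning delta across subjects.

**Infrastructure**: a seeded synthetic-cohort generator (shot outcomes,
full-body kinematics, paired real/virtual validation angles) with `evr`
and `real_world` presets; a 2D shot-physics simulator (median-of-10-frames
strike estimation, frictional ball dynamics, line-of-centres collision,
pocket test) and landmark-based frame calibration (planar similarity +
height ratio); CSV/JSON readers and writers and a small CLI.

## Worked example

```r
library(evrlearn)
cfg <- cohort_config(n_subjects = 10, n_trials = 300, seed = 1)  # EVR preset
b   <- run_analysis(cfg, include_kinematics = FALSE)

head(b$block_summary, 3)
#>   block n_subjects      mean       sd       sem
#> 1     1         10 13.166856 2.937799 0.9290135
#> 2     2         10 11.769449 2.535284 0.8017273
#> 3     3         10  9.713971 1.611589 0.5096291

d <- b$delta
sprintf("reduction: %.2f +/- %.2f deg (p = %.4f, n = %d)",
        d$mean, d$sd, d$p, d$n)
#> "reduction: 6.91 +/- 2.55 deg (p = 0.0000, n = 10)"

v <- run_validation_twin(seed = 1)   # real-vs-virtual angle twin
sprintf("twin: r = %.3f, RMSE = %.2f deg", v$angle$r, v$angle$rmse)
#> "twin: r = 0.995, RMSE = 2.67 deg"
```

The block summary shows the mean absolute directional error falling from
~13° (block 1) toward ~6° (block 12): the synthetic cohort's exponential
learning curve recovered by the robust block statistics. The delta is the
paired first-vs-last-block improvement across the 10 synthetic subjects;
the validation twin reproduces the near-unity angle correlation expected
when a 2.85° engine discrepancy perturbs shots spread uniformly over
±50°.

Command line (after install):

```sh
Rscript inst/cli/evrlearn analyze --subjects 10 --trials 300 --seed 1 --out out/
Rscript inst/cli/evrlearn validate --seed 1
```

## Layout

- `R/` — generator (`synthetic_cohort.R`), physics
  (`billiards_physics.R`), preprocessing (`kinematics_prep.R`),
  task-space (`shot_performance.R`) and body-space
  (`body_space_metrics.R`) metrics, curve fits (`learning_dynamics.R`),
  I/O + CLI (`io_cli.R`).
- `vignettes/evrlearn-methods.Rmd` — model assumptions, parameter
  defaults, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
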
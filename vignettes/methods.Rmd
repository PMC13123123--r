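---
title: "Simulating and analyzing planar robotic upper-limb assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing planar robotic upper-limb assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarreach)
```

`planarreach` implements the full analysis chain of a planar end-effector
robotic assessment of upper-limb function in children with unilateral
cerebral palsy (UCP): a synthetic-session generator, extraction of the five
device indices from raw 100 Hz position/force logs, feasibility-questionnaire
scoring, and the multivariate statistical pipeline. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot tell you.

## The assessment protocol being modelled

A child sits at the device, forearm strapped to a mobile handle
(manipulandum) that is tracked on an optically coded surface. Five
exercises are performed with each arm, less affected side (LAS) first:

* **Small/Large ROM** — centre-out reaching to 8 radial targets, enumerated
  clockwise from 12 o'clock, out and back, 16 movements, robot in free mode.
* **Small/Large 8-trajectory** — tracking a figure-eight under resistive
  guidance: deviation from the ideal path produces a restoring force
  `k1*d + k2*d^2` toward the nearest path point, capped at the device's
  50 N limit.
* **Coins** — transporting five coins from an arc to outer drop zones.

The device's published constraints are honoured throughout: 100 Hz
sampling, a 50 N force cap, a 0.8 m/s velocity cap, about 0.4 mm
system-level position accuracy and 0.01 N force accuracy.

The workspace geometry (target radii, eight-shape size, coin arc) is not
part of the device's public description; it is a configuration surface
(`workspace_config()`) with tabletop-plausible defaults: ROM radii
0.08/0.14 m, a lemniscate of Gerono (`x = a cos t`, `y = (a/2) sin 2t`)
with half-widths 0.06/0.12 m, coins at 0.10 m with drop zones 0.06 m
further out, task reference speeds 0.08–0.10 m/s. Geometry is a free
parameter of the artifact, not a claim about any particular installation.

## Movement model

Each discrete movement is a minimum-jerk point-to-point segment
(`10\tau^3 - 15\tau^4 + 6\tau^5`), the standard model of smooth reaching;
the figure-eight is traversed with a per-lap minimum-jerk arc-length
profile (2 laps by default). Impairment enters through
`impairment_profile()`:

| parameter | meaning | identity value |
|---|---|---|
| `speed_scale` | commanded mean speed relative to the task reference, in (0, 1] | 1 |
| `endpoint_jitter_sd` | SD (m) of the per-movement endpoint miss | 0 |
| `tremor_amplitude`, `tremor_freq` | 4–7 Hz action-tremor sinusoid (m, Hz) | 0 |
| `path_wander_sd` | SD (m) of 2 Hz low-pass-filtered positional wander | 0 |
| `submovement_count` | corrective submovements appended per movement | 0 |
| `effort_inefficiency` | drive-force multiplier, at least 1 | 1 |

Three modelling details matter for realism:

* *Hypermetria.* Impaired reaches overshoot: each endpoint aim adds a bias
  of `0.8 * endpoint_jitter_sd` along the movement direction, on top of the
  symmetric miss. This is what makes the covered-area index grow with
  severity, as dispersive reaching does in children with UCP.
* *Bounded misses.* Endpoint misses are Gaussian truncated at 1.5 SD —
  visual feedback (and, on constrained tasks, the guidance force) prevents
  gross drift. On the figure-eight no endpoint jitter applies at all: the
  path is tracked continuously, and deviation comes from tremor and wander.
* *Wander spectrum.* The wander is white noise through two cascaded
  one-pole filters at 2 Hz, rescaled analytically to its stationary SD, so
  its velocity content stays physiological instead of being dominated by
  sampling-rate noise.

The force channel models the user's drive force as proportional to the
instantaneous velocity (gain 40 N·s/m) times `effort_inefficiency`, minus
the guidance force on constrained tasks, plus load-cell noise; magnitudes
are capped at 50 N. This is deliberately mass-free: the device's real
dynamics are unpublished, and the model's only job is to make the work
integrals meaningful and impairment-sensitive.

## Sensing chain

Positions are not reported directly: per-step odometry increments (with
slip noise) are fused with absolute optical fixes (25 Hz, 0.4 mm SD) by a
linear Kalman filter on planar position (`localize_fuse()`), a constant-
position process driven by the odometry. The published description of the
real device mentions an Extended Kalman Filter whose state model is in an
unavailable supplement; the reconstruction here deliberately omits a
heading state, which would add unverifiable detail, and the tests verify
the filter against the discrete Riccati fixed point and against Monte-Carlo
RMSE of dead reckoning. Because sensing noise can nudge a speed-capped
trajectory over the cap, the recorded stream is re-clipped to 0.8 m/s — the
firmware reports controller-limited velocity.

## The five indices

`build_report()` computes exactly the indices the device records per task:
covered area only for the ROM tasks, accuracy error only for the
constrained tasks, and time, work and velocity everywhere.

Numerical choices:

* **Area**: 120 angular bins (`2*pi/120`, i.e. 3°) fixed by the index's
  definition; empty bins contribute zero; the per-bin maximum radius makes
  the index exactly `pi R^2` for a full circle of radius R.
* **Velocity**: central finite differences; below a stall threshold of
  1e-4 m/s the direction of motion is undefined and the sample contributes
  zero to the work integrals (the index definitions never define the unit
  velocity at zero speed).
* **Work**: trapezoidal integration on the sample grid; at 100 Hz this is
  within 1% of a 10 kHz dense integration for smooth reaches (tested).
* **Accuracy error**: nearest-point (not time-indexed) correspondence to
  the 1 mm-resolution reference polyline, because the tasks are self-paced
  and "distance from the ideal trajectory" is geometric. The search is
  coarse-to-fine; where the two branches of the lemniscate are nearly
  equidistant an isolated sample may resolve to the farther branch, with a
  pointwise error bounded by half the coarse spacing (≤ 5 mm) and a
  trial-mean effect below 0.1 mm (tested against an exhaustive 0.1 mm
  search).
* **Units**: SI internally; reports render accuracy error in mm and time in
  both seconds and minutes. The single "work" column of a device export
  maps to the total integral; the useful-work integral is reported as an
  extra column, since which of the two a given firmware exports is not
  specified.

## The cohort generator

`generate_cohort()` produces a complete synthetic study. Its defaults *are*
the study conditions: 28 children; manual-ability levels I/II = 16/12;
hand-function levels 4–8 with counts 5/8/3/8/4, hence severity groups
1 (levels 7–8, n = 12) and 2 (levels 4–6, n = 16); female/male 8/20;
right/left dominance 13/15; age 10.90 ± 3.32 years in 7–18; game
perception 17/28. Marginals are hit exactly at n = 28 and rescaled
proportionally otherwise.

A single latent severity factor links everything through a Gaussian copula:

* All latents (the severity factor and every innovation) share one
  truncated standard-normal law (±1.6 SD). The truncation reflects the
  study's inclusion criteria — a mild-to-moderate cohort with a bounded
  severity range — and, because every latent shares the same law, the
  correlation between any two latents is exactly the product of their
  severity loadings.
* Clinical scores (MA2 subscales, Box-and-Block counts) are monotone
  negative transforms of their latents, rounded and clipped to instrument
  ranges; classifications are assigned by severity rank with exact marginal
  counts.
* Impairment parameters scale as `exp(0.18 * imp)` in the limb-impairment
  latent (tremor and wander with a compressed exponent, 0.7 of that —
  tremor intensity is less strongly graded by clinical severity than effort
  and endpoint control), capped at 1.35 (guidance and feedback bound the
  achievable deviation), with the more affected side strictly worse:
  multiplicative contrasts of 1.5–1.7 on the noise channels, +0.5 on
  effort inefficiency, one extra submovement, and a 1.05 speed factor (the
  speed-over-accuracy pattern of the more affected side).
* Each limb also receives its own idiosyncratic pace/effort/noise
  variation. This is not cosmetic: it makes the two limbs exchangeable
  draws under a null configuration (`effect_scale = 0`), which is what
  gives the unpaired limb test its nominal type-I error. With variation
  only at the participant level the test would be radically conservative.
* Questionnaire items load on a respondent satisfaction latent
  (children 0.52, clinicians 0.47, calibrated so Cronbach's alpha centres
  near 0.82 and 0.76), with domain means near the top of the 5-point scale
  and responses rounded and clipped to 1–5.
* When a rank-correlation target is requested (`rank_target_work`), the
  Box-and-Block loading is solved from the Gaussian-copula identity
  `rho = 2 sin(pi r_s / 6)` with a fixed compensation factor (1.06) for the
  attenuation of the simulated measurement chain (instrument-range clipping
  ties, trial-level noise), estimated once from a large-n calibration run.
  At n = 500 the realized Spearman correlation lands within ±0.1 of the
  target (tested).

Trials are child-seeded (`child_seed()` hashes participant, limb and task
ids into the master seed), so any single trial can be regenerated in
isolation and the whole cohort is a pure function of `(n, config, seed)`.

## Statistical pipeline

One row per participant × limb (56 observations for 28 children) reproduces
the published analysis design, including its acknowledged caveat: the two
limbs of one child are not independent, and the multivariate model treats
them as if they were. The package reproduces the design rather than
"improving" it; the limb exchangeability of the generator keeps the test
honest under the null.

* **Screening**: Shapiro–Wilk per column (delegated to `stats`), IQR
  outliers outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with linear-interpolation
  (type 7) quartiles. Most simulated indices are non-normal (skewed
  severity scaling plus limb-pooling bimodality), while outlier flags on
  the primary outcomes are rare — matching a cohort in which no outliers
  were detected.
* **MANOVA**: for each task, two models — hand-function group or
  manual-ability level, never both (conceptual overlap and collinearity) —
  plus limb, dominance, and centred age. Each term is tested marginally:
  `H` is the extra residual cross-product of the model without the term,
  `E` the full-model residual cross-product, `V = tr[H(H+E)^{-1}]`, with
  the standard Pillai F approximation. With 4 responses and one-df terms
  this yields the familiar F(4, 48) at n = 56, and the multivariate partial
  eta squared `V/s` equals `V`. Factor coding is treatment with references
  LAS, group 1, level I and right. Follow-ups are univariate marginal F
  tests with Benjamini–Hochberg adjustment across the responses within one
  term (the closest literal reading of FDR-adjusted univariate analyses).
* **Correlations**: Spearman on average ranks with a t-approximation
  p-value, categorized as slight (< 0.20), low (0.20–0.40), moderate
  (0.40–0.70), high (0.70–0.90, inclusive), very strong (> 0.90); the
  clinical measures are correlated against the more-affected-side trials,
  since that is the limb the clinical scores describe.
* **Power**: the minimum n to detect a correlation uses the exact
  (Hotelling) distribution of the sample correlation with the critical
  value from the t distribution — for ρ = 0.53, α = .05 two-tailed, power
  .80 this gives n = 25, where the Fisher-z approximation gives 26 — and
  the enrolment target inflates by `ceil(n / (1 - rate))` (28 at 10%
  dropout). A noncentral-F approximation for a Pillai global effect is
  included for completeness; its result depends on design constants
  (group/response counts) that a study must supply.

## Problem sizes and determinism

The test suite regenerates everything from code: no stored fixtures. The
simulation-level guarantees are checked at the sizes the design states —
type-I error of the limb test on 1,000 null cohorts of n = 28 (small-eight
task), effect recovery and direction on 200 default cohorts, copula
fidelity at n = 500, screening over 50 cohorts — with every cohort a
deterministic function of its seed. Default trial durations are kept short
(two laps of the eight, single out-and-back reaches) so that a full cohort
simulates in seconds; the indices are duration-normalized or averaged, so
the analysis pipeline is unaffected by this choice.

## Limitations

* The movement model is kinematic: no joint torques, no trunk compensation,
  no biomechanical arm model; the force model is mass-free.
* The default limb contrast is deliberately clear-cut; the resulting limb
  effect sizes at n = 28 are larger than a typical clinical cohort would
  show. Passing the recovery tests demonstrates that the pipeline detects
  such effects, not that a real cohort of this size would yield them.
* The localization filter is a linear position-only reconstruction of a
  firmware EKF whose true state model is unpublished.
* Synthetic cohorts cannot reproduce dataset-dependent published values
  (cohort MANOVA tables, observed correlation matrices); those require the
  deposited dataset, for which a mapping-driven loader
  (`load_deposited_dataset()`) is provided but never required.
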
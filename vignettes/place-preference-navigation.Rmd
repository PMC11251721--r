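---
title: "Methods: simulating and analysing VR place-preference navigation"
author: "placenav developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing VR place-preference navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placenav)
```

## The task model

The package models a goal-directed navigation task for body-fixed rodents
in a two-dimensional virtual circular arena. The animal always starts at
the arena centre with one of six imposed start directions and must reach
one of two hidden reward zones: a high-value zone (12 reward drops)
centred at 180° and a low-value zone (2 drops) at 0°, a 6:1 value ratio.
Because heading in a body-fixed VR rig is expressed by rotating the scene,
the analysis works in the *allocentric scene direction*: the angular
position of the virtual scene shown at screen centre.

### Coordinate and angle conventions

Angles are measured in degrees **clockwise from East**, so that North is
270°, NE is 315°, NW is 225°, South is 90°, and the high-value zone sits
due West at 180°. This is a reflection of the usual counterclockwise math
convention (`theta_math = -theta_arena mod 360`); `angle_of()` and the
converters in the package handle it. Positions are continuous Cartesian
meters with the arena centre at the origin; trajectories are sampled at
60 Hz by default.

### Geometry defaults and their provenance

| quantity | default | status |
|---|---|---|
| arena radius | 0.8 m | task constant |
| departure circle radius | 0.10 m | task constant (~20 cm diameter) |
| perimeter boundary radius | 0.62 m | task constant (shortest start→zone path) |
| zone radial span | 0.62–0.78 m | assumption (inner edge fixed; outer edge "slightly off the wall") |
| zone angular half-width | 30° | assumption (only dashed depictions exist) |
| start directions | 270, 315, 45, 90, 135, 225 | task constant |
| ITI stillness | 5 s below 5 cm/s | task constant |
| reward delivery | 8 s | task constant |
| main-task trial timeout | 120 s | assumption (not stated for the main task) |
| probe reward-zone radius | 0.4 m | task constant |
| probe timeout | 60 s | task constant |

The zone angular extent and outer radius are genuinely undocumented; the
30° half-width makes each zone subtend one sixth of the circle, leaves
every start direction outside both zones, and is configurable through
`build_main_arena()` overrides. The probe task's two beacon positions are
assumed symmetric about the start heading (left/right of a north-facing
start from the south periphery), which the task's left/right trial design
implies.

## The generative agent model

`simulate_trial()` runs in two phases.

**Phase 1 (scene alignment).** If the agent's `rotate_at_start` flag is
set, a goal zone is drawn (low-value with probability `p_low_target`,
else high-value) and a goal angle is sampled as the zone centre plus von
Mises noise with concentration `kappa_align`. The scene rotates in place
at 90°/s in the direction of `turn_bias` (counterclockwise for trained
agents, mirroring the stereotypical body-turn that appears with
learning). The final rotation sample snaps exactly onto the goal angle:
the nominal 5° alignment tolerance is treated as a snap so that the
noise-free limit produces an exactly straight ray and the departure
directions are exactly von Mises distributed about the target — this
makes parameter recovery exact and is the one place we deviate from a
literal "stop within 5°" reading.

**Phase 2 (running).** The agent advances at a per-trial speed drawn from
a truncated normal (mean 0.15 m/s, sd 0.03, floor 0.05 — invented
defaults; the source behaviour is only reported as unchanged across
conditions) in steps of `speed / sample_rate` along the current heading
plus independent von Mises jitter (`kappa_run`). Reaching the wall
(radius ≥ arena radius − 0.02 m) records a *bump*, inserts a 1 s
stationary recovery pause, and triggers reorientation: with probability
`p_reorient_success` the agent re-aims at the goal zone centre, otherwise
at a uniformly random interior point (guaranteeing inward motion). The
trial ends on reward-zone entry or at timeout.

Per-trial seeds are derived arithmetically from `(session seed, trial
index)`, so sessions are reproducible and trials independently
replayable. Start directions come in shuffled balanced blocks of the six
options, so any multiple of six trials is exactly balanced.

### Condition defaults

| condition | `kappa_align` | `p_low_target` | `kappa_run` | rotate | `p_reorient` | bias |
|---|---|---|---|---|---|---|
| novice | 2 | 0.3 | 60 | no | 0.3 | none |
| expert | 40 | 0 | 200 | yes | 0.9 | ccw |
| dMUS | 8 | 0 | 100 | yes | 0.6 | ccw |
| iMUS | 1.5 | 0.2 | 60 | yes | 0.3 | ccw |
| probe | — | 0 | 150 | no | 1 | none |

These values are the package's calibration of the qualitative regimes,
chosen once from first principles and not tuned against test outcomes: a
von Mises sd of ~9° (κ = 40) keeps an expert inside the 30° zone
half-width on almost every trial; κ = 8 (~20° sd) makes the dorsal
inactivation agent miss the zone on roughly one trial in seven, with most
wall bumps near the goal; κ = 1.5 plus a 0.2 low-value targeting
probability makes the intermediate inactivation agent's departures
dispersed enough that visit percentage, crossing counts, and mean-vector
lengths all degrade, reproducing the ordering control < dorsal <
intermediate on every impairment measure. The simulator contains **no
learning rule**: the novice→expert transition is represented by distinct
parameter sets.

## Trajectory metrics

DD and PCD are defined as *positional* angles of boundary-crossing points
(not instantaneous headings): the first inside→outside crossing of the
departure circle and the perimeter boundary respectively, with the
crossing point linearly interpolated in Cartesian space between the
bracketing samples (tested to agree with 10× dense resampling within
0.5°). Only inside→outside perimeter transitions are counted as
crossings, so re-entries are free but every extra excursion costs one
count. Timeout trials have undefined DD/PCD (`NA` in metric tables) and
are excluded from angular aggregates but retained in visit-percentage
denominators; training criteria use the completed-trial denominator, and
both percentages are reported.

Excess travel distance subtracts the shortest possible path — the 0.62 m
perimeter radius for the main task (both zones share that inner edge, so
the zone actually entered does not change it) and the start-to-zone-edge
distance for the probe task. Mean speed covers the full start→end
interval including recovery pauses, since the source measure is not
defined more precisely; latency is clocked from trial onset (the
alternative, clocking from departure-circle exit, is recoverable from the
crossing time). Session duration adds 8 s of reward delivery per
completed trial and a 5 s inter-trial interval per trial to the summed
trial durations.

The scene-rotation trace pairs the *unwrapped* scene direction
(minimal-jump unwrapping; clockwise positive) with cumulative path length
normalized to [0, 1] between the start and the departure-circle exit, so
pre-departure in-place rotations appear as vertical excursions at
distance 0. `first_turn_direction()` thresholds the first unwrapped
excursion (default 10°) over the whole trial.

## Statistics

- **Kuiper two-sample test.** The statistic is the maximum-minus-minimum
  of the circular cumulative rank walk (equivalently
  `max(F_a − F_b) + max(F_b − F_a)`), which is invariant to the origin.
  P-values are obtained by label permutation rather than asymptotic
  series: small samples are handled exactly, at the cost of a seed and a
  permutation count in the configuration (default 10,000; the original
  analysis does not state which method it used, and permutation is our
  documented choice). With `n_perm = 499` the rejection rule p ≤ 0.05 is
  an exact level-0.05 test, which the suite verifies over 2,000 null
  pairs.
- **Watson–Williams test.** Standard one-way F for mean directions with
  the `1 + 3/(8κ̂)` correction, κ̂ from Fisher's approximation. Multi-group
  comparisons are supported. The result carries an `applicable` flag that
  is false when the average of the groups' mean resultant lengths is
  below 0.45 (after Batschelet); following the source's reporting style
  the gate *warns* rather than refuses, and pairwise contrasts in
  `compare_conditions()` carry the flag per pair.
- **Wilcoxon signed-rank.** Exact distribution for ≤ 25 untied non-zero
  differences, tie-corrected normal approximation otherwise; an all-ties
  comparison returns a flagged degenerate result. The dPBS/iPBS merge
  gate treats a degenerate comparison as "no difference", which makes
  `merge_pbs()` idempotent.
- **Repeated-measures ANOVA.** Within-subject F with Greenhouse–Geisser
  epsilon from the double-centred covariance of condition scores
  (bounded to [1/(k−1), 1]; identically 1 for k = 2), corrected and
  uncorrected p-values, and Bonferroni-corrected pairwise paired t-tests
  with multiplier equal to the number of pairs.
- Angular condition contrasts pool trials across subjects (the degrees of
  freedom of the source analyses imply trial-level pooling, which weights
  subjects by trial count); scalar contrasts are subject-level. Two-sided
  tests and α = 0.05 throughout.

## What the synthetic data establish — and what they do not

The generator reproduces the *statistical structure* the analyses
consume: balanced pseudorandom start directions, condition-dependent
departure concentration and low-value targeting, wall bumps with recovery
pauses, and 40/60-trial session shapes. It does not emulate learning
dynamics within a session, licking or reward-consumption microbehaviour,
landmark-identity effects, or realistic speed profiles (speeds are an
invented truncated normal). A green effect-direction test therefore
establishes that the pipeline *recovers the regimes it was pointed at* —
ordering of crossings, deviations and visit percentages across
conditions, PRE/POST learning contrasts — not that the simulator's
parameter values estimate any real animal's behaviour, and no test in
this package asserts the original study's F or p values.

## Numerical choices and degenerate inputs

Crossing interpolation solves the quadratic for the segment-circle
intersection and clamps the root to the segment. Samples landing exactly
on a boundary count as outside (`< r` to `>= r` transitions). The von
Mises sampler is Best–Fisher rejection; κ = 0 falls back to the circular
uniform and κ > 10⁶ (or infinite) to a point mass. `mean_vector()`
reports an undefined direction below a resultant length of 10⁻¹²;
`rm_anova()` returns F = 0, p = 1 for identical columns and epsilon 1
when the double-centred covariance vanishes. All-zero-difference Wilcoxon
input, empty circular samples, groups of one, incomplete subject ×
condition matrices, and malformed trajectory files are rejected with
specific errors.

## Known limitations

- The agent's per-step heading jitter is serially independent, so its
  paths are straighter than real trajectories of equal concentration;
  `kappa_run` is not comparable to any measurable path property.
- The reorientation model (aim at goal centre or a uniform interior
  point) is a two-mode caricature of post-bump behaviour.
- The probe task reuses a single parameter set across drug conditions,
  encoding the finding that beacon-guided navigation is insensitive to
  hippocampal inactivation rather than testing it.
- Watson–Williams assumes equal concentrations; only the 0.45 gate, not a
  homogeneity test, guards it — matching the source workflow.
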
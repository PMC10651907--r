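---
title: "From head and gaze streams to behavioral inference: the activegaze methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From head and gaze streams to behavioral inference: the activegaze methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the measurement problem

A freely moving observer compares two physical block-built (polycube) objects
mounted on posts in a 3.4 m x 4.3 m arena and answers a two-alternative
forced-choice question: are they the same object (geometric congruence) or
different? Unlike screen-based mental-rotation work, the observer walks,
turns, and trades eye movements against head and body movements. The
measurement system delivers two asynchronous streams: a 6-DOF head pose at a
nominal 120 Hz (position in meters plus a unit quaternion) and a gaze
direction in the head frame at a nominal 50 Hz, with roughly 0.2 mm RMSE
position error and about 1.42 degrees mean gaze-direction error.

`activegaze` turns those streams into per-trial behavioral measures and the
study's statistical inferences. Every stage is a plain function:

1. `synchronize()` — interpolate the head stream to the gaze timestamps and
   rotate gaze into the world frame;
2. `detect_fixations()` — velocity-threshold (I-VT) event classification;
3. `label_trial()` — assign each fixation to object 1, object 2, or
   environment from its mean world gaze ray;
4. `summarize_trial()` — response time, fixation counts, grouping profile,
   primary/secondary ratio, head-path length, correctness;
5. `rm_anova()` / `fit_accuracy_model()` — the inference layer.

A synthetic experiment generator (`generate_design()`, `simulate_trial()`,
`simulate_experiment()`) produces the same file formats with complete ground
truth, so the whole pipeline is testable end to end without any recorded
human data.

## Coordinate conventions

The world frame is right-handed with the x-y plane on the floor, z up, in
meters; the origin sits at the arena corner nearest the curtain behind which
the observer starts. Quaternions are stored `(w, x, y, z)` and canonicalized
to `w >= 0`; `q` and `-q` encode the same rotation. The head frame has +x
forward, +y left, +z up; gaze is stored as a unit direction in that frame —
the minimal device-independent representation, deliberately not a 2-D screen
point. Timestamps are trial-relative float seconds (t = 0 at the first head
sample).

## Synchronization

Gaze is the lower-rate, event-defining stream, so the head pose is
interpolated to each valid gaze timestamp: positions linearly, orientations
geodesically (slerp along the shorter arc). Head gaps longer than three
nominal head periods (25 ms) are not interpolated across; gaze samples
falling inside such gaps, outside the head span, or flagged invalid are
dropped with logged counts. The world gaze ray originates at the interpolated
head position and points along the head orientation applied to the head-frame
gaze direction.

## Fixation detection

A fixation is a maximal run of samples whose angular velocity stays below the
threshold. The estimator is a central difference over nearest neighbours
(40 ms span at 50 Hz) — the smallest-lag symmetric estimate — with one-sided
differences at the ends, and the angle between directions computed as the
arccos of the clamped dot product.

Tunable parameters, defaults, and rationale:

* `velocity_threshold` = 30 deg/s. The defining parameter of the event model.
* `min_duration` = 60 ms: runs shorter than a usable visual sample are
  discarded (standard I-VT event treatment).
* `max_gap` = 75 ms with `merge_angle` = 0.5 degrees: two runs separated by a
  brief super-threshold gap are fused only when their mean directions agree
  within half a degree, so noise-induced breaks heal but pre- and
  post-saccade fixations never merge. The consistency bound is an absolute
  angle, not a drift rate: any per-sample jitter already implies drift rates
  of degrees per second across a 40 ms gap, so a rate criterion would make
  merging vacuous.
* `frame` = `"world"`: velocity is computed on world-frame directions so that
  smooth head translation while fixating a static object (vestibulo-ocular
  stabilization) still counts as one fixation. Head-frame mode exists for
  data where the head pose is untrusted; with static stimuli and a moving
  observer the world frame is the behaviorally meaningful choice.

## Target assignment

Each object is summarized by a bounding sphere around its posed cell
centroid. For a fixation's mean ray, the *angular miss* with respect to an
object is the angle between the ray direction and the direction to the sphere
center, reduced by the sphere's angular radius (floored at zero; zero means
the ray pierces the sphere). The fixation is labeled with the object of
smallest miss if that miss is within `angular_tolerance` (default 1.42
degrees, the tracker's mean gaze accuracy — a fixation aimed at the limb
should not fall to "environment" because of tracker error), with ties broken
toward the nearer object; otherwise it is an environment fixation. At the
0.8-2 m viewing distances of this task a sphere bounding a <= 18 cm object
differs from the exact voxel hull by less than the gaze error, so exact
ray-voxel intersection would add complexity without adding information.
Shrinking the tolerance can only move labels toward "environment", never the
reverse — a monotonicity the tests check.

## Stimuli and congruence

Stimuli are polycubes: face-connected sets of lattice cells with 7, 10, or 18
blocks for the easy/medium/hard complexity levels, cell edge 0.03 m so an
18-block object fits the rough 12 x 14 x 18 cm physical envelope. Sameness is
geometric congruence under the 24 proper rotations of the cubic lattice:
`canonical_form()` translates the cells to the origin and takes the
lexicographically minimal sorted cell list over all 24 rotations, so
congruence is a string comparison of canonical forms. Mirror images are *not*
congruent — the stimuli are rigid physical objects and a chiral pair is
visually distinguishable — which the tests pin down with a chiral pentacube
and its mirror image. Random stimuli are grown by uniform face-adjacent
accretion; matching the published physical object set is a non-goal, since
nothing downstream depends on the particular shapes, only on block count and
congruence.

The orientation-difference factor (0/90/180 degrees) is realized by giving
both objects a common random rotation about the vertical post axis and
rotating the second by the requested angle about the same axis; the measured
`orientation_difference()` (geodesic angle between pose quaternions) then
equals the factor level exactly.

## Per-trial measures

* **Response time**: from the start of the trial's first fixation to the
  answer timestamp.
* **Fixation counts**: per label; analyses of "number of fixations" use
  object fixations only.
* **Grouping profile**: environment fixations are removed and the remaining
  object-label sequence is run-length encoded into bins 1..8 and "higher"
  (> 8), with shares as percentages of the number of runs. An environment
  glance does *not* split a run by default: a brief look at the floor
  mid-inspection should not end an inspection episode. A `split_on_environment`
  flag provides the stricter reading, since the original definition is
  ambiguous on this point.
* **Primary/secondary ratio**: shares over object fixations; the
  more-fixated object is primary; an exact tie goes to the object fixated
  first (deterministic, and the first-inspected object is the natural
  reference).
* **Head path**: anchored integration of the head positions with a 2 mm
  noise floor — displacement accumulates from the last anchor and is added
  only once it reaches `min_step`. Ten times the 0.2 mm RMSE tracker noise,
  the floor suppresses essentially all stationary jitter (i.i.d. noise never
  accumulates 2 mm of displacement from an anchor) while walking steps of
  several millimeters per 120 Hz frame pass through unchanged. On noiseless
  data the floor is unnecessary and `min_step = 0` (the naive polyline sum)
  is the exact measure; the recovery tests use it there.
* **Normalized response time**: mean response time divided by the block
  count of the complexity level, reported to two decimals — the per-element
  processing-time summary used to compare complexity levels.

## Statistical layer

Continuous measures use classical repeated-measures ANOVA on per-subject cell
means: trials are first averaged within subject x level (the random factor
assignment makes trial counts per cell unbalanced), then the within-subject
F is formed with df `(k - 1, (k - 1)(m - 1))` — `(2, 92)` for a 3-level
factor and `(5, 230)` for the 6-level trial-block factor at 47 subjects. A
subject missing a factor level is a design error by default, never silently
imputed; `on_missing = "drop_subjects"` drops incomplete subjects per effect
and records the count. No sphericity correction is applied by default;
`gg_correction = TRUE` adjusts p with the Greenhouse-Geisser epsilon. Fitting
is delegated to `stats::aov` error strata — the package's contribution is the
aggregation, df bookkeeping and reporting, and a from-scratch sums-of-squares
oracle in the tests pins the delegation down.

Accuracy sits near ceiling, so it gets a binomial mixed model instead: logit
link, subject random intercept, fixed effects for complexity, start position,
orientation difference, sameness, and trial block, fitted with `lme4::glmer`
and tested per term with Wald chi-squares on the coefficient blocks. The
learning-effect blocking — six consecutive blocks of three trials — is an
inference from the within-subject df the design implies (5 x 46 = 230 at 47
subjects) rather than a stated procedure, and is configurable. `nAGQ = 0` is
the default: in 150-replication null simulations at the study design (47
subjects x 18 trials, accuracy 0.9, subject effect SD 0.5) its Wald tests
rejected at 2-7% per effect at a nominal 5%, while the Laplace fit's Wald
tests ran at 9-16%; it is also about twenty times faster. `nAGQ = 1` remains
available. Complete separation (constant accuracy) is flagged with a warning
rather than crashing.

Whether the models should include interaction terms is left open by the
design; `rm_anova(..., interactions = TRUE)` tests all two-way interactions
on subject x cell tables where those tables are complete, which at 18 trials
per subject is realistic only for coarse factor pairs.

## The synthetic experiment

The generator's defaults are the study conditions: 47 subjects x 18 trials
(846 trials), complexity balanced 6/6/6 within subject and the other factors
uniform; 120/50 Hz sampling; the arena, post, and start-position geometry
(in line with the posts `P_s`, on the perpendicular bisector `P_l`, oblique
`P_c` — only the topology is fixed by the design, the coordinates are
configurable); per-complexity mean object-fixation counts of 76.56, 79.53 and
121.06 (log-normal across trials, floor of 6); per-complexity answer
accuracies 0.961, 0.9418, 0.912; a categorical grouping-size distribution
with shares 18.70, 18.43, 12.26, 8.57, 6.71, 4.87, 3.74, 3.23 and 18.41
percent for run lengths 1..8 and > 8; head joint limits (pitch 60, roll 40,
yaw 70 degrees) as simulator parameters; walking speed 0.8 m/s and log-normal
fixation durations (median 0.30 s, sdlog 0.35, clamped to 0.16-1.2 s) as
plausible values for an unhurried indoor task. These behavioral defaults are
simulator *inputs* seeded from the aggregate levels the task is known to
produce; recovery tests always compare pipeline output against the
*configured* values, never against published numbers, so the comparison is
never circular.

A trial unfolds as an itinerary on the 20 ms gaze grid: a short hold facing
the curtain, a turn, a walk to a vantage point sampled on an arc around the
posts (avoiding the post axis so the two objects stay angularly separated),
then groups of fixations drawn from the grouping distribution with strictly
alternating target objects, occasional floor glances, and occasional walks to
new vantage points during which the agent fixates a floor point ahead of its
destination (chosen with verified angular clearance from both objects).
Group sizes are drawn i.i.d. until the scheduled object-fixation count is
reached, with the last group kept whole, so the realized run-length
distribution is an unbiased sample of the configured one.

Two constructions make the noiseless streams exactly recoverable, which is
what turns the simulator into a test oracle:

* **Transitions.** Saccade-like direction changes between fixations follow a
  step profile built so that, under the 40 ms central-difference estimator,
  every scheduled fixation sample stays strictly below the 30 deg/s threshold
  and every transition sample stays strictly above it — including the
  boundary samples whose difference straddles the transition. Consecutive
  fixation targets are kept at least 2 degrees apart (re-sampled within the
  object, or routed through a small via-point when two targets nearly
  coincide), which bounds every margin away from the threshold by at least
  5 deg/s.
* **Consistency of emission and reconstruction.** The head stream is the
  ground truth: gaze-time head poses are defined by the same interpolation
  the pipeline applies (linear positions, slerp orientations between 120 Hz
  samples), and the emitted head-frame gaze direction is the world direction
  rotated by exactly that pose. Reconstruction error is then identically
  zero rather than merely small. Head orientation itself tracks the current
  gaze anchor through a double exponential smoother — a cosmetic choice that
  shapes eye-in-head angles but cannot affect recovery.

Sensor noise is injected after the ground truth is logged. Head positions
receive i.i.d. 0.2 mm per-axis Gaussian noise. Gaze error is decomposed into
a per-trial systematic offset (calibration error, the dominant component of a
mobile tracker's "mean accuracy") plus small per-sample jitter (precision,
SD 0.12 degrees per tangent axis), with the offset scale set so the expected
mean angular error equals 1.42 degrees. Under this decomposition a *single*
trial's mean error varies with its offset draw (the offset magnitude is
Rayleigh); the calibration is therefore checked as a Monte-Carlo expectation
over many offset draws, and velocities within a fixation see only the small
jitter, which is what real trackers show. A small probability (0.005) of
invalid gaze samples exercises the dropout path; both noise and dropout are
disabled together in the zero-noise suites.

What the simulator does **not** emulate: realistic saccade main-sequence
dynamics (transitions move at tens to hundreds of degrees per second, fast
enough to classify correctly but slower than biological saccades), gait
dynamics and head bob, smooth pursuit, blinks as a physiological process,
depth-from-vergence, strategy development across trials (no built-in learning
effect), and any dependence of fixation counts on orientation difference or
sameness. Passing the recovery suites therefore demonstrates that the
pipeline measures what the streams contain at the stated noise levels — not
that it would reproduce any particular empirical effect structure in recorded
human data.

## Numerical choices and degenerate inputs

Unit-norm checks use 1e-6 tolerances on ingest and 1e-9 internally; dot
products are clamped before `acos`. Slerp falls back to normalized linear
interpolation within 1e-6 radians of parallelism. A gaze ray originating
inside a bounding sphere (the observer's head inside an object — possible
only with corrupt data) is assigned to that object with a warning. Zero
object fixations make the ratio undefined and flag the trial rather than
dropping it; an empty label sequence yields an all-zero grouping profile.
Canonical forms break ties deterministically by lexicographic order, so
congruence is exactly transitive. Streams are written with fixed 9-decimal
formatting, making re-runs byte-identical and round-trips exact to 1e-9.

## Problem sizes in the test suites

The test and acceptance suites run the full pipeline at desk scale: 50
noiseless trials for exact recovery; 500 noisy trials for grouping-share
recovery (with label agreement and count error measured on the first 100);
200 null replications for each test statistic's type-I error and 100
replications for effect-sign recovery at an odds ratio of 3; cohorts of 6-8
subjects for the workflow scripts. These sizes give the binomial and
multinomial checks their stated power while keeping a full run in the
minutes range on one CPU; all of them are parameters of the tests, not of
the package.

## Known limitations

* Bounding-sphere assignment cannot resolve fixations to parts of an object;
  per-block areas of interest would need ray-voxel intersection.
* The I-VT classifier has no explicit smooth-pursuit class; slow pursuit of a
  (hypothetically) moving target would be absorbed into fixations.
* The GLMM reports raw per-term p values; no multiplicity adjustment across
  dependent measures is applied or claimed.
* The simulator's locomotion and itinerary model is deliberately simple; it
  is a stand-in with known ground truth, not a behavioral model of human
  strategy.
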
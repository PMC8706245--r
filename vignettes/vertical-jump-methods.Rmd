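---
title: "Methods: jump analysis, recruitment optimization and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jump analysis, recruitment optimization and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpkin)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices, and the
limits of what the synthetic validation can show.

## The movement and its phases

A countermovement vertical jump is a stretch-shortening-cycle action. The
package divides it into five periods delimited by six events: quiet upright
standing ends at movement onset (*compression* begins), the deepest knee
squat starts the *pushing* phase, the feet leaving the ground start
*flight*, ground contact starts *landing*, the deepest landing squat starts
the recovery to *standing*, which ends when the jumper is quiet again. All
intervals are half-open frame ranges `[start, end)` on the 100 Hz marker
clock, so the five phase durations always sum exactly to the analysed span.

Event detection uses the most informative signal for each boundary:

* **takeoff / touchdown** — the summed vertical ground reaction force (GRF)
  crossing a 10 N threshold (about 5 % of a 20 kg child's weight; parameter
  `threshold_n`). Unloaded runs are debounced: loaded gaps of up to 2
  frames inside a flight interval are treated as noise spikes.
* **squat reversals** — the frame of minimal included knee angle before
  takeoff and after touchdown. The raw argmin is refined by fitting a cubic
  to a ±10-frame window and taking the stationary point nearest the raw
  frame: averaging over the window suppresses the multi-frame jitter a
  pointwise argmin has under marker noise, and the cubic term absorbs the
  different curvatures on the two sides of the reversal.
* **upright boundaries** — a two-stage detector. Quiet standing is coarsely
  located where the knee angle stays within 5° of its initial value and the
  (4 Hz-smoothed) pelvis-marker midpoint moves slower than 20 mm/s for at
  least 0.1 s. The boundary is then sharpened on the GRF: force responds to
  acceleration, one differentiation earlier than any position channel, so
  movement onset is the first sustained deviation from body weight
  exceeding `max(6, 5 * MAD)` newtons (body weight and noise scale are
  estimated robustly from the quiet run, which may bleed a few frames into
  the movement).

## Joint kinematics

All angles are *included* angles between marker rays projected onto the lab
sagittal (Y–Z) plane, with +Z up and +Y the facing direction: hip
(ASIS–trochanter–femoral epicondyle, vertex at the trochanter), knee
(trochanter–epicondyle–malleolus), ankle (epicondyle–malleolus–fifth
metatarsal head), and the signed forward tilt of the trunk line (clavicle
midpoint to T10) from vertical. Full extension reads near 180°, deep
flexion small; with this convention "maximum flexion" is the *minimum* of
the included angle series.

Ranges of motion and peak angular velocities are taken over *closed* phase
intervals: each phase runs from one delimiting posture to the next, and the
extremum at the closing boundary (the squat itself) belongs to the phase's
excursion. Angular velocity uses central differences of the 10 Hz-filtered
angle series with no further smoothing — the filter already bounds noise
amplification, and documenting the estimator keeps results reproducible.
Vertical excursions (squat depth, flight height, landing buffer depth) are
measured at the posterior-superior-iliac-spine midpoint relative to its
mean height over the pre-jump quiet-standing window (the pre-jump stand
only, not the final stand).

Filtering follows gait-lab convention: 4th-order zero-phase Butterworth
(two 2nd-order passes, forward–backward) at 10 Hz for markers and 20 Hz for
force channels, with odd-symmetric reflection padding so the first and last
tenths of a second are not corrupted by edge transients. Force plates
(250 Hz) are resampled onto the marker clock by anti-aliased decimation
(zero-phase low-pass at 0.45 of the target rate, then linear interpolation
over the common span); kinematic events are defined on the marker clock,
which is why the GRF moves rather than the markers.

## Inverse dynamics and muscle recruitment

Net sagittal joint moments come from planar bottom-up Newton–Euler over
foot, shank and thigh: the plate force applied at the centre of pressure
loads the foot, and each segment passes its proximal reaction up the chain.
Segment masses, centre-of-mass positions and radii of gyration are
documented Winter-style fractions scaled to the child's mass and measured
segment lengths (`segment_params()`). Moments are reported
extensor-positive (plantarflexion, knee extension, hip extension). Frames
whose plate force is below 20 N are excluded from recruitment: as the force
vanishes the centre of pressure is numerically undefined and the implied
moments are artifacts.

Muscle redundancy — more muscles than balance equations — is resolved by a
recruitment criterion on the activations $a_i = f_i / N_i$, where $N_i$ is
the muscle's current tensile strength:

* the **polynomial criterion** $G = \sum_i a_i^{\,p}$, $p \ge 1$, solved as
  a quadratic program at $p = 2$ (the default), as a linear program at
  $p = 1$, and otherwise by a log-barrier interior method on the null space
  of the moment-arm matrix, warm-started along a homotopy in $p$ (large
  powers are too ill-conditioned to attack directly);
* the **min/max criterion** $G = \max_i a_i$ — the "lowest physiological
  fatigue" strategy — via the linear program *minimize* $t$ subject to
  $Cf = d$, $0 \le f_i \le N_i t$, with ties among optimal vertices broken
  by the minimum-norm force vector, and a bisection-on-$t$ fallback when
  the simplex stalls.

Both enforce the equality residual $\lVert Cf - d\rVert_\infty \le
10^{-6}(1 + \lVert d\rVert_\infty)$ and non-negativity to $10^{-9}$. As
$p \to \infty$ the polynomial optimum approaches the min/max optimum; the
finite-$p$ gap on the peak activation is provably inside
$[t^*,\, t^* k^{1/p}]$ for $k$ muscles, which is the tolerance the tests
assert on random problems (at $p = 100$ and activations of order one this
gap is larger than any fixed $10^{-3}$).

The shipped muscle model is a reduced planar set of eight actuators
spanning ankle, knee and hip with constant sagittal moment arms and
strengths proportional to body weight; the conventional 31-muscle naming
maps onto these groups via `muscle_group_labels()`. With a single actuator
standing in for each anatomical group, per-actuator force rankings are not
directly comparable to a fine-grained musculoskeletal reconstruction: in
particular, when a large trunk tilt is recovered inside a very short push,
the hip-extensor actuator can carry the largest single-actuator force even
though a many-muscle model attributes the maximum to a knee extensor. For a
mature-*depth* jump (crouch angle inside 60–90°) the knee-extensor group
carries the largest pushing-phase force under both criteria, which is the
ordering the tests assert.

## Developmental stage classification

The qualitative stage descriptions are made quantitative and reproducible:
a jump without a two-foot takeoff (per-plate takeoff frames more than 3
frames apart) is *initial*; a two-foot jump whose crouch angle — the
included knee angle at maximum squat — lies in [60°, 90°] with the body
fully extended at takeoff is *mature*; every other two-foot jump is
*primary*. "Fully extended" means hip and knee included angles within 20°
of their quiet-standing values: the hip's marker-defined included angle
reads well below 180° even in neutral posture, so upright stance is the
meaningful extension reference. The crouch angle is taken as the included
angle (a deep squat between 60° and 90° is only meaningful on that
convention). All thresholds are arguments.

## Cohort statistics

The statistical layer mirrors common practice for unbalanced
stage-by-age designs: least-squares fits with sum-to-zero contrasts and
Type III sums of squares (switchable to Type II), partial
$\eta^2 = SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} + SS_{\mathrm{error}})$,
and LSD pairwise $t$ tests on the two-way pooled error mean square with
unadjusted $p$ values. When a design cell is empty the interaction is
inestimable; the model falls back to main effects and flags the result.

Stepwise regression is the forward-entry/backward-removal procedure with
entry at $p < 0.05$ and removal at $p > 0.10$ (both arguments). Entry stops
when the current fit is numerically exact ($R^2 > 1 - 10^{-10}$), since
partial-$F$ tests on a residual at the noise floor are meaningless. The
final model reports unstandardized and standardized coefficients
($\beta = b\, s_x / s_y$), tolerance and VIF
($\mathrm{VIF}_j = 1 / (1 - R_j^2)$), the Durbin–Watson statistic
$\sum (e_t - e_{t-1})^2 / \sum e_t^2$, and $R^2$.

## The synthetic generator

`generate_trial()` drives a planar four-segment chain (foot, shank, thigh,
pelvis+trunk) with closed-form trajectories chosen so that every quantity
the pipeline estimates has an exactly known construction value:

* The pelvis height is piecewise polynomial: a quintic descent ending with
  upward acceleration `turn_accel_ms2` (default 3 m/s², i.e. about 1.3 body
  weights at the reversal — a genuine parabolic extremum that survives
  noise), a quintic push ending exactly at the ballistic takeoff velocity
  $v_0 = gT/2$ with acceleration $-g$, exact ballistic flight, a
  monotone absorbing landing profile $|v|(u) = v_0 (1-u)(1+cu)$ whose
  coefficient is fixed by the buffer depth, and a quintic recovery. The
  segments are acceleration-matched at every boundary, so the GRF is
  continuous and rolls smoothly to zero at takeoff.
* Leg angles follow from two-link inverse geometry with the hip kept above
  the ankle; the law of cosines gives the knee included angle directly from
  the hip height, so knee flexion extrema fall exactly on the phase
  boundaries. Standing posture keeps 1 % knee flexion: at full extension
  the two-link geometry is singular and joint angular accelerations blow
  up, which is also why real knees never fully lock during dynamic tasks.
* Takeoff extension is a heel raise of `takeoff_extension` times half the
  foot length; the trunk re-extends over the first 70 % of the push
  (proximal-to-distal sequencing, as jumpers do), and the centre of
  pressure migrates from under the centre of mass to the forefoot as the
  heel rises.
* The vertical GRF is computed on the force-plate clock from the
  whole-body centre of mass, $F = m(\ddot z_{COM} + g)$, split equally over
  two plates; it is identically zero on flight frames. Gaussian noise is
  added last at the profile's SDs.

A profile whose durations and depths are dynamically impossible (pelvis
trajectory non-monotone within a phase, hip beyond leg reach, or stance GRF
negative) is rejected with a "kinematically inconsistent profile" error.

`solve_profile()` inverts the geometry for requested metric targets: squat
depth from knee ROM (law of cosines, closed form), flight time from flight
height, pushing duration from peak hip angular velocity (1-D root solve on
the measured, filter-emulated metric), takeoff extension from ankle landing
ROM, and spine tilt directly. Because faster hip drives demand more than
1 g of downward pelvis acceleration under some geometries, the solver
recruits more pelvic tilt (and, when the squat is not pinned by a knee
target, a deeper squat) before shortening the push further — the
co-adjustments faster jumpers actually show. After a knee-target solve the
flight time, pushing time and buffer are re-tied to the squat depth so a
shallow countermovement produces a proportionally lower jump.

Default conditions model a 4-year-old (109.1 cm, 18.4 kg; segment lengths
as standard stature fractions): 150 mm squat, 0.45 s compression, 0.25 s
push, 0.30 s flight, 110 mm landing buffer, 35° peak spine tilt, and
measurement noise of 2 mm (markers) and 5 N (plates) when enabled. Group
samplers ship stage-level and age-level target distributions for spine
tilt, knee pushing ROM, ankle landing ROM and hip pushing angular velocity;
one printed dispersion (0.0520 rad/s for the youngest group) is an order of
magnitude below every comparable value and is treated as a typographical
anomaly (default 0.52, literal value available via `literal_sd = TRUE`).

**Realization accuracy.** Through the full filtered pipeline, solved
targets come back within ~0.03 rad/s for hip angular velocity, ~0.5° for
spine tilt, ~1° for knee ROM, and within about +3° for ankle landing ROM —
the ankle angle changes tens of degrees across a handful of landing frames,
so ±1 frame of boundary discretization moves the measured range by a few
degrees. Group *differences* are unaffected by this common offset; tests on
absolute means therefore use hip angular velocity.

**What passing tests do and do not show.** The generator provides exact
ground truth for boundaries, ballistics, rigid geometry and force
consistency, which validates the estimators' correctness and their noise
robustness at realistic noise levels. It does not emulate soft-tissue
artifact, marker occlusion patterns, asymmetric or multi-plane movement,
arm swing, or trial-to-trial within-subject variability — conclusions about
real recordings still require the usual data-quality checks.

## The flight-height regression layer

For validating the regression tooling, `generate_regression_cohort()` draws
the five predictors (ankle pushing ROM, spine tilt, hip angular velocity,
and two body-weight-normalized muscle forces) from distributions spanning
the cohort group means, adds three uncorrelated decoys, and sets the
outcome to the deterministic linear model plus Gaussian noise; with
`noise_sd = NULL` the residual SD is calibrated analytically so the
population $R^2$ equals the requested value (default 0.64). Three decoys
keep the probability that none slips past a 0.05 entry threshold near
$0.95^3 \approx 0.86$, so exact-support recovery remains a meaningful
check.

## Problem sizes and runtime choices

The test-suite simulations are sized to finish in well under a minute:
25-trial Monte Carlos for the noisy segmentation and squat-depth checks,
25 random recruitment problems per criterion against exact enumeration
oracles, and 12-seed selection checks for stepwise regression. The
acceptance script scales the same checks up (100 noisy trials, 100 random
problems, 100 stepwise seeds at $n = 500$) and completes in about twenty
seconds on one core.

## Known limitations

* Strictly planar: mediolateral coordinates are constant plus noise, and
  only sagittal angles are computed.
* The reduced muscle set exercises the recruitment formulations fully but
  is not an anatomical reconstruction; per-muscle force magnitudes are
  model-relative (see above on group rankings).
* Constant moment arms: no angle-dependence of muscle leverage.
* The upright-boundary detector assumes force-plate data are present;
  purely kinematic trials would need a different onset rule.
* CSV (plus a YAML sidecar) is the interchange format; binary capture
  formats should be exported to CSV upstream.
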
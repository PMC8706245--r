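# jumpkin

Biomechanical analysis of children's countermovement vertical jumps from
marker-based motion capture and force-plate recordings.

A vertical jump is a stretch-shortening-cycle movement: the jumper squats
(compression), drives upward (pushing), leaves the ground (flight), absorbs
the impact (landing) and returns to quiet standing. `jumpkin` implements the
full analysis chain a movement-development study needs, end to end:

* **Trial I/O** — wide-CSV marker trajectories (mm, 100 Hz) and force-plate
  records (N, 250 Hz), zero-phase 4th-order Butterworth smoothing (10 Hz
  markers / 20 Hz kinetics), and anti-aliased synchronization of the plates
  onto the marker clock.
* **Segmentation** — the five jump phases delimited by quiet standing, the
  maximum knee squat, a 10 N ground-reaction flight threshold and the
  landing squat, plus classification into the initial / primary / mature
  developmental stages from the crouch angle, takeoff extension and two-foot
  takeoff.
* **Kinematics** — sagittal-projected included joint angles (hip, knee,
  ankle), forward spine tilt, per-phase ranges of motion, peak angular
  velocities, squat depth, flight height and landing buffer depth; flight
  height `h` obeys the ballistic identity `h = g T^2 / 8` for flight time
  `T`.
* **Musculoskeletal layer** — planar bottom-up Newton–Euler inverse dynamics
  (net ankle/knee/hip moments, extensor-positive) and redundant
  muscle-recruitment optimization over a reduced eight-actuator model:
  minimize the polynomial criterion `G = sum_i (f_i / N_i)^p` (`p >= 1`) or
  the min/max criterion `G = max_i f_i / N_i`, subject to the moment balance
  `C f = d` and tensile non-negativity `f >= 0`; peak forces are reported
  per body weight (N/BW).
* **Cohort statistics** — two-way ANOVA (stage x age, Type III sums of
  squares) with partial eta-squared, Fisher's LSD post-hoc on the pooled
  error term, and SPSS-style stepwise linear regression with standardized
  betas, tolerance/VIF and Durbin–Watson diagnostics.
* **Synthetic jumps** — a planar four-segment generator that produces
  marker and force-plate data with exactly known phase boundaries, ballistic
  flight, rigid segments and GRF consistent with the whole-body centre of
  mass, so every downstream stage is testable without subject data. A
  profile solver inverts the geometry to realize requested joint-level
  targets, and cohort samplers draw groups with specified metric means/SDs.

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
methods on fitted objects, `autoplot()` methods for trials, moments and
muscle forces.

## Worked example

```r
library(jumpkin)

# a jump whose knee pushing ROM and peak spine tilt hit requested values
profile <- solve_profile(list(knee_rom_pushing_deg = 70.315,
                              spine_max_tilt_deg  = 44.223))
trial <- generate_trial(profile, seed = 42)
trial
#> <jump_trial> subject SYN01, age group 4, stage unknown
#>   markers: 16 labels x 271 frames @ 100 Hz
#>   grf: 2 plate(s) x 676 frames @ 250 Hz

proc   <- preprocess_trial(trial)   # 10/20 Hz smoothing + synchronization
phases <- segment_trial(proc)
phases
#> <jump_phases>
#> # A tibble: 5 x 3
#>   phase       start   end
#> 1 compression    51    96
#> 2 pushing        96   122
#> 3 flight        122   149
#> 4 landing       149   176
#> 5 standing      176   221

jump_metrics(proc, phases)[, c("flight_time_s", "flight_height_mm",
                               "squat_depth_mm", "knee_rom_pushing_deg",
                               "spine_max_tilt_deg")]
#> flight_time_s 0.27, flight_height_mm 152.9, squat_depth_mm 140.3,
#> knee_rom_pushing_deg 70.8, spine_max_tilt_deg 44.6
```

The flight lasted 0.27 s, so the ballistic rise is `9.81 * 0.27^2 / 8 =
89.4 mm`; the remaining 63 mm of the 152.9 mm flight height is the heel
raise at takeoff. The requested knee ROM (70.3 deg) and spine tilt
(44.2 deg) come back within a degree through the full filtered pipeline.

```r
stage_from_trial(proc, phases)
#>   stage   knee_crouch_angle_deg extension_at_takeoff two_foot_takeoff
#> 1 primary                  93.4 TRUE                 TRUE

# net joint moments -> per-muscle forces over the push, normalized to BW
forces <- muscle_forces(proc, phases, phases_use = "pushing")
head(dplyr::arrange(forces, dplyr::desc(peak_force_bw)), 4)
#>   muscle peak_force_n peak_force_bw peak_activation
#> 1 RF             640.          3.55           1.77
#> 2 GMAX           564.          3.12           0.892
#> 3 VAS            413.          2.29           0.572
#> 4 HAM            377.          2.09           0.835
```

The crouch angle of 93.4 deg (just above the 60–90 deg window) classifies
this jump as primary stage. Cohort-level tools follow the same grammar:

```r
trials <- sample_cohort(group_specs_stage(), n_per_group = 10, seed = 1)
tbl <- cohort_metrics(trials)
tidy(two_way_anova(tbl, "flight_height_mm"))
tidy(stepwise_regression(generate_regression_cohort(500, seed = 1),
                         "flight_height_mm",
                         setdiff(names(generate_regression_cohort(10, seed = 1)),
                                 "flight_height_mm")))
```

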
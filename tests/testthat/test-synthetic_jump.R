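test_that("flight apex follows the ballistic closed form", {
  pr <- ballistic_profile(0.4)
  tr <- generate_trial(pr, seed = 1)
  psis <- (tr$markers$LPSI_Z + tr$markers$RPSI_Z) / 2
  apex_rise_m <- (max(psis) - tr$truth$z_upright_mm -
                    tr$truth$extension_mm) / 1000
  expect_equal(apex_rise_m, 9.81 * 0.4^2 / 8, tolerance = 1e-4 / 0.2)
  expect_lt(abs(apex_rise_m - 9.81 * 0.4^2 / 8), 1e-4)
})

test_that("generation is deterministic under a seed", {
  pr <- jump_profile(marker_noise_sd_mm = 2, grf_noise_sd_n = 5)
  a <- generate_trial(pr, seed = 7)
  b <- generate_trial(pr, seed = 7)
  expect_identical(a$markers, b$markers)
  expect_identical(a$grf, b$grf)
  c <- generate_trial(pr, seed = 8)
  expect_false(identical(a$markers, c$markers))
})

test_that("requested knee pushing ROM is realized through the pipeline", {
  pr <- solve_profile(list(knee_rom_pushing_deg = 70.315))
  tr <- generate_trial(pr, seed = 3)
  proc <- preprocess_trial(tr, NULL, NULL, antialias = FALSE)
  m <- jump_metrics(proc, segment_trial(proc))
  expect_lt(abs(m$knee_rom_pushing_deg - 70.315), 0.5)
})

test_that("GRF is zero in flight and positive on stance, with consistent impulse", {
  tr <- clean_trial()$raw
  ev <- tr$truth$events
  dtm <- 1 / 100
  fz <- total_vertical_grf(tr$grf)
  t_to <- (ev[["takeoff"]] - 1) * dtm
  t_td <- (ev[["touchdown"]] - 1) * dtm
  in_flight <- fz$time_s >= t_to - 1e-9 & fz$time_s < t_td - 1e-9
  expect_true(all(fz$fz_total[in_flight] == 0))
  expect_true(all(fz$fz_total[!in_flight] > 0))
  # pushing-phase impulse balances takeoff momentum plus gravity
  t_ms <- (ev[["max_squat"]] - 1) * dtm
  push <- fz$time_s >= t_ms & fz$time_s < t_to
  dt_g <- 1 / 250
  impulse <- sum(fz$fz_total[push]) * dt_g
  m <- tr$anthro$mass_kg
  t_push <- t_to - t_ms
  expected <- m * (tr$truth$v0_mm_s / 1000 + 9.81 * t_push)
  expect_lt(abs(impulse / expected - 1), 0.01)
})

test_that("segment lengths are rigid over the whole trial", {
  mk <- clean_trial()$raw$markers
  seglen <- function(a, b) {
    sqrt((mk[[paste0(a, "_Y")]] - mk[[paste0(b, "_Y")]])^2 +
           (mk[[paste0(a, "_Z")]] - mk[[paste0(b, "_Z")]])^2)
  }
  for (pair in list(c("RANK", "RKNE"), c("RKNE", "RGT"), c("CLAV", "T10"))) {
    len <- seglen(pair[1], pair[2])
    expect_lt(max(len) - min(len), 1e-6)
  }
})

test_that("infeasible profiles are rejected with informative errors", {
  expect_error(jump_profile(squat_depth_mm = 500), "leg reach")
  expect_error(jump_profile(t_landing = 2), "landing absorption")
  expect_error(jump_profile(t_flight = -0.1), "> 0")
  expect_error(generate_trial(jump_profile(t_pushing = 0.45)),
               "kinematically inconsistent")
})

test_that("profile solver realizes combined group targets", {
  targets <- list(spine_max_tilt_deg = 44.223, knee_rom_pushing_deg = 70.315,
                  hip_max_angvel_pushing_rad_s = 10.463)
  pr <- solve_profile(targets)
  tr <- generate_trial(pr, seed = 4)
  proc <- preprocess_trial(tr)
  m <- jump_metrics(proc, segment_trial(proc))
  expect_lt(abs(m$spine_max_tilt_deg - 44.223), 1)
  expect_lt(abs(m$knee_rom_pushing_deg - 70.315), 1.5)
  expect_lt(abs(m$hip_max_angvel_pushing_rad_s / 10.463 - 1), 0.02)
})

test_that("cohort sampling reproduces group means and is seed-stable", {
  specs <- group_specs_age()
  specs <- specs[specs$metric == "hip_max_angvel_pushing_rad_s" &
                   specs$age_group == 5L, ]
  specs$n <- 6
  trials <- sample_cohort(specs, seed = 21)
  expect_length(trials, 6)
  cm <- cohort_metrics(trials)
  # 6 draws from N(10.946, 0.436): mean within 4 SE of the target
  expect_lt(abs(mean(cm$hip_max_angvel_pushing_rad_s) - 10.946),
            4 * 0.436 / sqrt(6) + 0.05)
  # degenerate case: SD 0 realizes the mean nearly exactly
  s0 <- specs[1, ]; s0$sd <- 0; s0$n <- 1
  t0 <- sample_cohort(s0, seed = 5)
  m0 <- cohort_metrics(t0)
  expect_lt(abs(m0$hip_max_angvel_pushing_rad_s - 10.946), 0.1)
  # different seeds give different cohorts
  t2 <- sample_cohort(specs, seed = 22)
  expect_false(identical(cohort_metrics(t2)$hip_max_angvel_pushing_rad_s,
                         cm$hip_max_angvel_pushing_rad_s))
})

test_that("regression cohort embeds the printed flight-height equation", {
  eq <- flight_height_equation()
  zero <- tibble::as_tibble(setNames(as.list(rep(0, 5)), eq$term[-1]))
  expect_equal(predict_flight_height(zero), -85.527)
  coh <- generate_regression_cohort(80, noise_sd = 0, seed = 2)
  fit <- lm(stats::reformulate(eq$term[-1], "flight_height_mm"), data = coh)
  expect_equal(unname(coef(fit)), eq$estimate, tolerance = 1e-8)
  expect_lt(max(abs(coef(fit) - setNames(eq$estimate, eq$term))), 1e-6)
  # decoys are present and uncorrelated by construction
  expect_true(all(paste0("decoy_", 1:3) %in% names(coh)))
  # calibrated noise puts the population R^2 near the requested value
  set.seed(9)
  big <- generate_regression_cohort(4000, r_squared = 0.64, seed = 9)
  fit2 <- lm(stats::reformulate(eq$term[-1], "flight_height_mm"), data = big)
  expect_lt(abs(summary(fit2)$r.squared - 0.64), 0.05)
})
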
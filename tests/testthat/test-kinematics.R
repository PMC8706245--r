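test_that("projected angles reproduce hand-computed values", {
  expect_equal(projected_angle(c(0, 0, 1), c(0, 0, 0), c(0, 1, 0)), 90)
  # collinear points open to a straight angle
  expect_equal(projected_angle(c(0, 0, 2), c(0, 0, 1), c(0, 0, -3)), 180)
  # dot-product oracle: cos = 4/5
  expect_equal(projected_angle(c(0, 1, 2), c(0, 0, 0), c(0, 2, 1)),
               acos(4 / 5) * 180 / pi, tolerance = 1e-10)
  expect_error(projected_angle(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "degenerate")
})

test_that("projected angles are invariant to scaling, translation and mediolateral shifts", {
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    base <- projected_angle(a, b, c)
    s <- runif(1, 0.1, 10)
    expect_equal(projected_angle(b + s * (a - b), b, b + s * (c - b)), base,
                 tolerance = 1e-8)
    shift <- rnorm(3)
    expect_equal(projected_angle(a + shift, b + shift, c + shift), base,
                 tolerance = 1e-8)
    # any displacement along the mediolateral (X) axis is projected away
    dx <- c(rnorm(1), 0, 0)
    expect_equal(projected_angle(a + dx, b, c), base, tolerance = 1e-8)
  }
})

test_that("spine tilt is the signed angle from vertical", {
  expect_equal(spine_tilt(c(0, 0, 400), c(0, 0, 100)), 0)
  expect_equal(spine_tilt(c(0, 300, 0), c(0, 0, 0)), 90)
  expect_equal(spine_tilt(c(0, 1, 1), c(0, 0, 0)), 45, tolerance = 1e-10)
  # backward lean is negative
  expect_lt(spine_tilt(c(0, -1, 3), c(0, 0, 0)), 0)
  expect_error(spine_tilt(c(0, 1, 1), c(0, 1, 1)), "degenerate")
})

test_that("phase ROM is the max-minus-min over the interval", {
  expect_equal(phase_rom(rep(42, 50), c(1, 51)), 0)
  expect_equal(phase_rom(c(100, 80, 60, 90), c(1, 5)), 40)
  expect_error(phase_rom(1:10, c(5, 5)), "interval")
})

test_that("peak angular velocity matches a constant-rate oracle", {
  rate <- 100
  ramp <- seq(90, 0, length.out = 26)  # 90 deg over 0.25 s = 2*pi rad/s
  expect_equal(max_angular_velocity(ramp, c(2, 25), rate), 2 * pi,
               tolerance = 0.01)
  expect_equal(max_angular_velocity(rep(33, 30), c(1, 31), rate), 0)
  expect_error(max_angular_velocity(1:30, c(1, 3), rate), "3 frames")
})

test_that("spatiotemporal metrics follow the generator's construction", {
  # flight height decomposes into takeoff extension plus ballistic rise
  an <- suppressWarnings(anthropometrics(109.1, 18.4))
  ext60 <- 60 / (0.5 * an$foot_cm * 10)
  pr <- jump_profile(t_flight = 0.4, squat_depth_mm = 230, t_pushing = 0.33,
                     buffer_depth_mm = 180, takeoff_extension = ext60,
                     t_landing = (180 + 60) / (0.42 * 1000 * 9.81 * 0.2))
  tr <- generate_trial(pr, seed = 11)
  proc <- preprocess_trial(tr, NULL, NULL, antialias = FALSE)
  m <- jump_metrics(proc, segment_trial(proc))
  expect_lt(abs(m$flight_height_mm - (60 + 1000 * 9.81 * 0.16 / 8)), 1)
  expect_lt(abs(m$squat_depth_mm - 230), 0.5)
  expect_lt(abs(m$flight_time_s - 0.4), 0.011)
  # phase times reproduce the profile durations
  expect_lt(abs(m$compression_time_s - pr$t_compression), 0.011)
  expect_lt(abs(m$pushing_time_s - pr$t_pushing), 0.011)
})

test_that("squat depth survives marker noise", {
  errs <- sapply(1:20, function(i) {
    tr <- generate_trial(jump_profile(marker_noise_sd_mm = 2,
                                      grf_noise_sd_n = 5), seed = 600 + i)
    proc <- preprocess_trial(tr)
    m <- tryCatch(jump_metrics(proc, suppressWarnings(segment_trial(proc))),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    m$squat_depth_mm - 150
  })
  expect_gte(mean(abs(errs) <= 2, na.rm = TRUE), 0.9)
})

test_that("zero-noise metrics agree with the profile targets", {
  pr <- solve_profile(list(spine_max_tilt_deg = 44.223,
                           knee_rom_pushing_deg = 70.315,
                           hip_max_angvel_pushing_rad_s = 10.463))
  tr <- generate_trial(pr, seed = 12)
  proc <- preprocess_trial(tr, NULL, NULL, antialias = FALSE)
  m <- jump_metrics(proc, segment_trial(proc))
  expect_lt(abs(m$spine_max_tilt_deg - 44.223), 0.5)
  expect_lt(abs(m$knee_rom_pushing_deg - 70.315), 0.5)
  expect_lt(abs(m$squat_depth_mm - pr$squat_depth_mm), 2)
  # ballistic consistency of the measured metrics
  rise <- m$flight_height_mm - pr$geom$E
  expect_lt(abs(rise / (1000 * 9.81 * pr$t_flight^2 / 8) - 1), 0.01)
})

test_that("a trial with no countermovement reports zero squat depth", {
  fx <- clean_trial()
  ph <- fx$phases
  # force the squat event onto the upright boundary: the measured depth
  # must collapse to the upright reference level
  ph2 <- ph
  ph2$events[["max_squat"]] <- ph$events[["upright_start"]]
  ph2$phases$end[ph2$phases$phase == "compression"] <-
    ph2$events[["max_squat"]]
  ph2$phases$start[ph2$phases$phase == "pushing"] <-
    ph2$events[["max_squat"]]
  m <- jump_metrics(fx$proc, ph2)
  expect_lt(abs(m$squat_depth_mm), 0.5)
})

test_that("ROM over a union of intervals dominates the parts", {
  ja <- joint_angles(clean_trial()$proc$markers)
  ph <- clean_trial()$phases$phases
  comp <- c(ph$start[1], ph$end[1])
  push <- c(ph$start[2], ph$end[2])
  whole <- c(comp[1], push[2])
  expect_gte(phase_rom(ja$knee_deg, whole),
             max(phase_rom(ja$knee_deg, comp), phase_rom(ja$knee_deg, push)))
})
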
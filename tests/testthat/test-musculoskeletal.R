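test_that("segment parameters scale linearly with body mass", {
  an <- suppressWarnings(anthropometrics(109.1, 20))
  seg <- segment_params(an)
  expect_lte(sum(seg$mass_kg[seg$segment != "hat"] * 2) +
               seg$mass_kg[seg$segment == "hat"], 20 + 1e-9)
  an2 <- suppressWarnings(anthropometrics(109.1, 40))
  seg2 <- segment_params(an2)
  expect_equal(seg2$mass_kg, 2 * seg$mass_kg)
  expect_equal(seg$mass_kg, seg$mass_fraction * 20)
  expect_equal(seg$length_m[seg$segment == "shank"], an$shank_cm / 100)
})

static_trial <- function(cop_offset_mm = 50, n = 60) {
  base <- clean_trial()$raw
  mk <- base$markers[rep(1, n), ]
  mk$time_s <- seq(0, by = 0.01, length.out = n)
  m <- base$anthro$mass_kg
  grf <- dplyr::bind_rows(lapply(1:2, function(pl) {
    tibble::tibble(time_s = mk$time_s, plate = pl, fz = m * 9.81 / 2,
                   fy = 0, cop_y = mk$RANK_Y[1] + cop_offset_mm)
  }))
  jump_trial(mk, dplyr::arrange(grf, time_s, plate), base$anthro)
}

test_that("static standing reproduces the closed-form ankle moment", {
  tr <- static_trial(50)
  mom <- inverse_dynamics(tr)
  m <- tr$anthro$mass_kg
  seg <- segment_params(tr$anthro)
  m_foot <- seg$mass_kg[seg$segment == "foot"]
  heel_y <- tr$markers$RTOE_Y[1] - 0.9 * tr$anthro$foot_cm * 10
  foot_com_y <- (heel_y + tr$markers$RTOE_Y[1]) / 2
  expected <- (m * 9.81 / 2) * 0.05 -
    m_foot * 9.81 * (foot_com_y - tr$markers$RANK_Y[1]) / 1000
  i <- 30
  expect_lt(abs(mom$ankle_nm[i] / expected - 1), 0.01)
  # plantarflexion demand grows with an anterior centre of pressure
  expect_gt(inverse_dynamics(static_trial(80))$ankle_nm[30], mom$ankle_nm[i])
})

test_that("flight moments vanish for ballistic segments", {
  fx <- clean_trial()
  mom <- inverse_dynamics(fx$proc, fx$phases)
  fl <- which(mom$in_flight)
  inner <- fl[fl > min(fl) + 2 & fl < max(fl) - 2]
  expect_lt(max(abs(c(mom$ankle_nm[inner], mom$knee_nm[inner],
                      mom$hip_nm[inner]))), 0.5)
})

test_that("moments match an independently coded single-frame Newton-Euler oracle", {
  fx <- clean_trial()
  tr <- fx$proc
  mom <- inverse_dynamics(tr, fx$phases)
  mk <- tr$markers
  seg <- segment_params(tr$anthro)
  gp <- tr$grf[tr$grf$plate == 2, ]
  dt <- 0.01
  yz <- function(l) cbind(mk[[paste0(l, "_Y")]], mk[[paste0(l, "_Z")]]) / 1000
  pts <- list(ankle = yz("RANK"), knee = yz("RKNE"), hip = yz("RGT"),
              toe = yz("RTOE"), heel = yz("RHEE"))
  d2 <- function(x, i) (x[i + 1, ] - 2 * x[i, ] + x[i - 1, ]) / dt^2
  ang <- function(a, b) atan2(a[, 2] - b[, 2], a[, 1] - b[, 1])
  for (i in c(100, 110, 140, 160)) {
    # oracle: textbook planar Newton-Euler, distal to proximal
    g <- 9.81
    pr <- list(foot = "ankle", shank = "knee", thigh = "hip")
    ds <- list(foot = NULL, shank = "ankle", thigh = "knee")
    fd <- c(gp$fy[i], gp$fz[i]); pd <- c(gp$cop_y[i] / 1000, 0); md <- 0
    oracle <- c()
    for (s in c("foot", "shank", "thigh")) {
      p <- seg[seg$segment == s, ]
      if (s == "foot") {
        com_s <- pts$heel + 0.5 * (pts$toe - pts$heel)
        th <- ang(pts$toe, pts$heel)
      } else {
        com_s <- pts[[pr[[s]]]] +
          p$com_fraction * (pts[[ds[[s]]]] - pts[[pr[[s]]]])
        th <- ang(pts[[pr[[s]]]], pts[[ds[[s]]]])
      }
      a_com <- d2(com_s, i)
      alpha <- (th[i + 1] - 2 * th[i] + th[i - 1]) / dt^2
      inert <- p$mass_kg * (p$gyration_fraction * p$length_m)^2
      pp <- pts[[pr[[s]]]][i, ]
      fp <- p$mass_kg * a_com + c(0, p$mass_kg * g) - fd
      cr <- function(r, f) r[1] * f[2] - r[2] * f[1]
      mp <- inert * alpha - md - cr(pd - com_s[i, ], fd) -
        cr(pp - com_s[i, ], fp)
      oracle[s] <- mp
      fd <- -fp; md <- -mp; pd <- pp
    }
    expect_lt(abs(-oracle[["foot"]] - mom$ankle_nm[i]), 1e-6)
    expect_lt(abs(oracle[["shank"]] - mom$knee_nm[i]), 1e-6)
    expect_lt(abs(-oracle[["thigh"]] - mom$hip_nm[i]), 1e-6)
  }
})

test_that("forced and symmetric recruitment problems solve in closed form", {
  s1 <- solve_recruitment(matrix(2), 10, 100)
  expect_equal(s1$f, 5)
  expect_equal(s1$objective, (5 / 100)^2)
  s2 <- solve_recruitment(matrix(c(1, 1), 1), 10, c(50, 50))
  expect_equal(s2$f, c(5, 5), tolerance = 1e-8)
  s3 <- solve_recruitment(matrix(c(1, 1), 1), 10, c(50, 50), "minmax")
  expect_equal(s3$objective, 0.1, tolerance = 1e-8)
  expect_equal(s3$f, c(5, 5), tolerance = 1e-6)
  expect_error(solve_recruitment(matrix(1), 1, 1, p = 0.5), "p must be")
  # infeasible: a single muscle cannot produce a negative moment
  si <- solve_recruitment(matrix(1), -5, 100)
  expect_equal(si$status, "infeasible")
})

test_that("solvers agree with enumeration oracles on random problems", {
  set.seed(77)
  for (i in 1:25) {
    pb <- random_recruitment_problem()
    p2 <- solve_recruitment(pb$C, pb$d, pb$strengths)
    or2 <- p2_enumeration_oracle(pb$C, pb$d, pb$strengths)
    expect_equal(p2$status, "optimal")
    expect_lt(max(abs(p2$f - or2$f)), 1e-3)
    mm <- solve_recruitment(pb$C, pb$d, pb$strengths, "minmax")
    orm <- minmax_vertex_oracle(pb$C, pb$d, pb$strengths)
    expect_lt(abs(mm$objective - orm$value), 1e-6)
    expect_lt(max(abs(pb$C %*% mm$f - pb$d)),
              1e-6 * (1 + max(abs(pb$d))))
  }
})

test_that("the polynomial criterion approaches min/max as p grows", {
  C <- matrix(c(1, 1, 2), 1); d <- 10; N <- c(100, 50, 80)
  hi <- solve_recruitment(C, d, N, p = 100)
  mm <- solve_recruitment(C, d, N, "minmax")
  expect_lt(max(abs(hi$activations - mm$activations)), 1e-3)
  set.seed(5)
  for (i in 1:5) {
    pb <- random_recruitment_problem()
    hi <- solve_recruitment(pb$C, pb$d, pb$strengths, p = 100)
    mm <- solve_recruitment(pb$C, pb$d, pb$strengths, "minmax")
    # provable bracket for the finite-p gap:
    # t* <= max activation(p) <= t* k^(1/p)
    k <- ncol(pb$C)
    expect_gte(max(hi$activations), mm$objective - 1e-6)
    expect_lte(max(hi$activations),
               mm$objective * k^(1 / 100) + 1e-6)
    # p = 2 cannot beat min/max on the max-activation metric
    p2 <- solve_recruitment(pb$C, pb$d, pb$strengths, p = 2)
    expect_gte(max(p2$activations), mm$objective - 1e-8)
  }
})

test_that("recruitment is homogeneous and monotone in the muscle set", {
  set.seed(8)
  pb <- random_recruitment_problem()
  lam <- 2.5
  for (crit in c("polynomial", "minmax")) {
    a <- solve_recruitment(pb$C, pb$d, pb$strengths, crit)
    b <- solve_recruitment(pb$C, lam * pb$d, pb$strengths, crit)
    expect_equal(b$f, lam * a$f, tolerance = 1e-5)
  }
  # adding a muscle never increases the min/max objective
  mm <- solve_recruitment(pb$C, pb$d, pb$strengths, "minmax")
  C2 <- cbind(pb$C, rnorm(nrow(pb$C), 0, 0.04))
  mm2 <- solve_recruitment(C2, pb$d, c(pb$strengths, 500), "minmax")
  expect_lte(mm2$objective, mm$objective + 1e-9)
})

test_that("the muscle-force pipeline matches closed forms and scale invariance", {
  fx <- filtered_trial()
  # one muscle per joint: forces are |moment| / arm, normalized by weight
  toy <- tibble::tibble(
    muscle = c("A", "K", "H"),
    arm_ankle_m = c(0.05, 0, 0), arm_knee_m = c(0, 0.05, 0),
    arm_hip_m = c(0, 0, 0.05), strength_n = c(1e4, 1e4, 1e4))
  mom <- inverse_dynamics(fx$proc, fx$phases)
  stance <- !mom$in_flight &
    mom$frame >= fx$phases$events[["upright_start"]] &
    mom$frame < fx$phases$events[["upright_end"]]
  fz2 <- fx$proc$grf$fz[fx$proc$grf$plate == 2]
  stance <- stance & fz2 >= 20
  ok <- stance & mom$ankle_nm >= 0 & mom$knee_nm >= 0 & mom$hip_nm >= 0
  mf <- suppressWarnings(muscle_forces(fx$proc, fx$phases, model = toy))
  bw <- fx$proc$anthro$mass_kg * 9.81
  expect_equal(mf$peak_force_bw[1], max(mom$ankle_nm[ok]) / 0.05 / bw,
               tolerance = 0.05)
  # doubling mass with doubled forces leaves N/BW unchanged
  tr2 <- fx$proc
  tr2$anthro$mass_kg <- 2 * tr2$anthro$mass_kg
  tr2$grf$fz <- 2 * tr2$grf$fz
  tr2$grf$fy <- 2 * tr2$grf$fy
  m1 <- muscle_forces(fx$proc, fx$phases)
  m2 <- muscle_forces(tr2, fx$phases)
  expect_equal(m2$peak_force_bw, m1$peak_force_bw, tolerance = 0.01)
})

test_that("knee extensors dominate the push of a mature-depth jump", {
  pr <- solve_profile(list(knee_rom_pushing_deg = 88))
  tr <- generate_trial(pr, seed = 2)
  proc <- preprocess_trial(tr)
  ph <- segment_trial(proc)
  grp <- c(VAS = "knee_ext", RF = "knee_ext", HAM = "hip_ext",
           GMAX = "hip_ext", SOL = "ankle", GAS = "ankle", TA = "ankle",
           ILPS = "hip_flex")
  for (crit in c("polynomial", "minmax")) {
    mf <- suppressWarnings(
      muscle_forces(proc, ph, criterion = crit, phases_use = "pushing"))
    gf <- tapply(mf$peak_force_n, grp[mf$muscle], max)
    expect_equal(names(which.max(gf)), "knee_ext", info = crit)
  }
  # the labels of the full muscle list all map onto modelled groups
  lbl <- muscle_group_labels()
  expect_equal(nrow(lbl), 31)
  expect_true(all(lbl$group %in% default_muscle_model()$muscle))
})
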
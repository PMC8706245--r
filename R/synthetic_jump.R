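#' Synthetic jump profile
#'
#' Parameters of one simulated countermovement vertical jump. The generator
#' drives a planar (sagittal) four-segment chain -- foot, shank, thigh,
#' pelvis+trunk -- with smooth polynomial trajectories: minimum-jerk pelvis
#' descent during compression, a monotone cubic-velocity push ending at the
#' ballistic takeoff velocity `g*t_flight/2`, frozen posture in flight, a
#' monotone absorbing profile in landing, and minimum-jerk recovery. Joint
#' angles follow from two-link inverse geometry (hip kept above the ankle),
#' so knee flexion extrema fall exactly on the phase boundaries.
#'
#' @param t_stand_pre,t_compression,t_pushing,t_flight,t_landing,t_standing,t_stand_post
#'   Phase durations in seconds (quiet stance, descent to maximum squat, push
#'   to takeoff, flight, touchdown to maximum landing squat, recovery to
#'   upright, final quiet stance).
#' @param squat_depth_mm Pelvis drop from upright to maximum squat.
#' @param buffer_depth_mm Pelvis drop below upright at maximum landing squat.
#' @param takeoff_extension Fraction in \[0, 1\] of the maximal heel raise
#'   (half the foot length) reached at takeoff; sets how much the body is
#'   extended above upright stance when the feet leave the ground.
#' @param spine_max_tilt_deg Peak forward trunk tilt at maximum squat.
#' @param landing_tilt_frac Landing-phase trunk tilt as a fraction of
#'   `spine_max_tilt_deg`.
#' @param pelvis_tilt_ratio Pelvic forward tilt as a fraction of trunk tilt.
#' @param turn_accel_ms2 Upward pelvis acceleration at the two squat
#'   reversals, m/s^2; sets how sharply the countermovement turns around
#'   (GRF at the reversal is about `(1 + turn_accel_ms2 / g)` body weights).
#' @param marker_noise_sd_mm,grf_noise_sd_n Gaussian measurement noise SDs.
#' @param rate_markers,rate_grf Sampling rates, Hz.
#' @param anthro An [anthropometrics()] row.
#' @return A list of class `jump_profile`.
#' @export
jump_profile <- function(t_stand_pre = 0.5, t_compression = 0.45,
                         t_pushing = 0.25, t_flight = 0.30,
                         t_landing = 0.24, t_standing = 0.45,
                         t_stand_post = 0.5,
                         squat_depth_mm = 150, buffer_depth_mm = 110,
                         takeoff_extension = 0.6,
                         turn_accel_ms2 = 3,
                         spine_max_tilt_deg = 35, landing_tilt_frac = 0.5,
                         pelvis_tilt_ratio = 0.5,
                         marker_noise_sd_mm = 0, grf_noise_sd_n = 0,
                         rate_markers = 100, rate_grf = 250,
                         anthro = NULL) {
  p <- list(t_stand_pre = t_stand_pre, t_compression = t_compression,
            t_pushing = t_pushing, t_flight = t_flight,
            t_landing = t_landing, t_standing = t_standing,
            t_stand_post = t_stand_post,
            squat_depth_mm = squat_depth_mm,
            buffer_depth_mm = buffer_depth_mm,
            takeoff_extension = takeoff_extension,
            turn_accel_ms2 = turn_accel_ms2,
            spine_max_tilt_deg = spine_max_tilt_deg,
            landing_tilt_frac = landing_tilt_frac,
            pelvis_tilt_ratio = pelvis_tilt_ratio,
            marker_noise_sd_mm = marker_noise_sd_mm,
            grf_noise_sd_n = grf_noise_sd_n,
            rate_markers = rate_markers, rate_grf = rate_grf,
            anthro = anthro %||%
              suppressWarnings(anthropometrics(109.1, 18.4)))
  class(p) <- "jump_profile"
  validate_profile(p)
}

# Derived geometry and feasibility checks. Returns the profile augmented
# with the quantities every downstream evaluation needs.
validate_profile <- function(p) {
  durs <- unlist(p[c("t_stand_pre", "t_compression", "t_pushing", "t_flight",
                     "t_landing", "t_standing", "t_stand_post")])
  if (any(durs <= 0)) abort("all phase durations must be > 0")
  if (p$squat_depth_mm < 0 || p$buffer_depth_mm < 0) {
    abort("squat and buffer depths must be >= 0")
  }
  if (p$takeoff_extension < 0 || p$takeoff_extension > 1) {
    abort("takeoff_extension must lie in [0, 1]")
  }
  if (p$marker_noise_sd_mm < 0 || p$grf_noise_sd_n < 0) {
    abort("noise SDs must be >= 0")
  }
  an <- p$anthro
  g <- list()
  g$Ls <- an$shank_cm * 10          # ankle-to-knee, mm
  g$Lt <- an$thigh_cm * 10          # knee-to-hip, mm
  g$z_ankle <- 0.039 * an$height_cm * 10
  g$H0 <- 0.99 * (g$Ls + g$Lt)      # hip height above ankle, upright (slight standing knee flexion keeps the two-link geometry away from its singularity)
  g$z_up <- g$z_ankle + g$H0
  g$E <- p$takeoff_extension * 0.5 * an$foot_cm * 10
  g$v0 <- 1000 * G_MS2 * p$t_flight / 2     # takeoff velocity, mm/s
  g$H_sq <- g$H0 - p$squat_depth_mm
  # knee included angle at a given hip height
  kang <- function(H) {
    acos(pmin(1, pmax(-1, (g$Ls^2 + g$Lt^2 - H^2) / (2 * g$Ls * g$Lt))))
  }
  g$knee_fun <- kang
  if (g$H_sq <= abs(g$Ls - g$Lt) || kang(g$H_sq) < 20 * pi / 180) {
    abort("kinematically inconsistent profile: squat depth exceeds leg reach")
  }
  if (p$turn_accel_ms2 <= 0) abort("turn_accel_ms2 must be > 0")
  # landing absorption: |v|(u) = v0 (1-u)(1+cu) must decay monotonically
  # (c in [-1, 1]) for the plate force to stay non-negative
  land_ratio <- (p$buffer_depth_mm + g$E) / (g$v0 * p$t_landing)
  g$c_land <- 6 * (land_ratio - 0.5)
  if (g$c_land < -1 || g$c_land > 1) {
    abort(paste0("kinematically inconsistent profile: landing absorption ",
                 sprintf("ratio %.2f outside [1/3, 0.58]", land_ratio),
                 " (adjust t_landing or buffer_depth_mm)"))
  }
  p$geom <- g
  p
}

# evaluates the trajectories on a fine grid and rejects profiles whose
# quintic segments would overshoot (non-monotone squat or extension, hip
# height beyond leg reach, negative stance GRF)
validate_dynamics <- function(p) {
  Tb <- profile_times(p)
  t <- seq(0, Tb[7], by = 0.002)
  st <- profile_state(p, t)
  mono_ok <- function(ph, dir) {
    zz <- st$z[st$phase == ph]
    all(dir * diff(zz) >= -1e-9)
  }
  if (!mono_ok("compression", -1) || !mono_ok("pushing", 1) ||
      !mono_ok("landing", -1) || !mono_ok("standing", 1)) {
    abort(paste0("kinematically inconsistent profile: pelvis trajectory is",
                 " not monotone within a phase (phase durations too long for",
                 " the displacement)"))
  }
  # whole-body COM acceleration must not exceed free fall during stance
  pts <- body_points(p, t)
  stance_idx <- which(st$phase != "flight")
  for (seg in split(stance_idx, cumsum(c(1, diff(stance_idx) > 1)))) {
    az <- second_diff(pts$com[seg, "z"], 0.002) / 1000
    if (min(az + G_MS2) < -1e-3) {
      abort("kinematically inconsistent profile: stance GRF would be negative")
    }
  }
  invisible(p)
}

# quintic Hermite segment: position/velocity/acceleration prescribed at
# both ends; u in [0, 1], duration Td
qhermite <- function(u, Td, p0, v0, a0, p1, v1, a1) {
  h00 <- 1 - 10 * u^3 + 15 * u^4 - 6 * u^5
  h10 <- u - 6 * u^3 + 8 * u^4 - 3 * u^5
  h20 <- 0.5 * u^2 - 1.5 * u^3 + 1.5 * u^4 - 0.5 * u^5
  h01 <- 10 * u^3 - 15 * u^4 + 6 * u^5
  h11 <- -4 * u^3 + 7 * u^4 - 3 * u^5
  h21 <- 0.5 * u^3 - u^4 + 0.5 * u^5
  p0 * h00 + v0 * Td * h10 + a0 * Td^2 * h20 +
    p1 * h01 + v1 * Td * h11 + a1 * Td^2 * h21
}

#' @export
print.jump_profile <- function(x, ...) {
  cat(sprintf(paste0("<jump_profile> squat %.0f mm, flight %.2f s ",
                     "(apex %.1f mm), noise %.1f mm / %.1f N\n"),
              x$squat_depth_mm, x$t_flight,
              1000 * G_MS2 * x$t_flight^2 / 8,
              x$marker_noise_sd_mm, x$grf_noise_sd_n))
  invisible(x)
}

# minimum-jerk unit step and phase boundary times
minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

profile_times <- function(p) {
  cumsum(c(stand_pre = p$t_stand_pre, compression = p$t_compression,
           pushing = p$t_pushing, flight = p$t_flight,
           landing = p$t_landing, standing = p$t_standing,
           stand_post = p$t_stand_post))
}

# Pelvis height z(t), hip-above-ankle H(t), trunk tilt theta(t) (rad) and
# pelvic tilt phi(t), all vectorized over t. Each stance phase is a quintic
# Hermite segment; boundary accelerations are matched across phases (-g at
# takeoff and touchdown, +turn_accel at the two squat reversals) so the GRF
# is continuous, tends smoothly to zero at the flight boundaries, and the
# squat reversals are genuine parabolic extrema.
profile_state <- function(p, t) {
  p <- validate_profile(p)
  g <- p$geom
  Tb <- profile_times(p)
  D <- p$squat_depth_mm; B <- p$buffer_depth_mm; E <- g$E; v0 <- g$v0
  g_mm <- 1000 * G_MS2
  a_turn <- 1000 * p$turn_accel_ms2
  z_to <- g$z_up + E

  z <- rep(g$z_up, length(t))
  H <- rep(g$H0, length(t))
  theta <- numeric(length(t))
  phase <- character(length(t))

  i <- t < Tb[1]
  phase[i] <- "stand_pre"

  i <- t >= Tb[1] & t < Tb[2]
  u <- (t[i] - Tb[1]) / p$t_compression
  z[i] <- qhermite(u, p$t_compression, g$z_up, 0, 0, g$z_up - D, 0, a_turn)
  H[i] <- pmin(z[i] - g$z_ankle, g$H0)
  theta[i] <- p$spine_max_tilt_deg * minjerk(u) * pi / 180
  phase[i] <- "compression"

  i <- t >= Tb[2] & t < Tb[3]
  u <- (t[i] - Tb[2]) / p$t_pushing
  z[i] <- qhermite(u, p$t_pushing, g$z_up - D, 0, a_turn, z_to, v0, -g_mm)
  e <- qhermite(u, p$t_pushing, 0, 0, 0, E, v0, -g_mm)
  H[i] <- pmin(z[i] - g$z_ankle - e, g$H0)
  # proximal-to-distal sequencing: the trunk finishes re-extending by 70%
  # of the push, before the legs and ankles complete takeoff
  theta[i] <- p$spine_max_tilt_deg * (1 - minjerk(pmin(1, u / 0.7))) * pi / 180
  phase[i] <- "pushing"

  i <- t >= Tb[3] & t < Tb[4]
  tau <- t[i] - Tb[3]
  z[i] <- z_to + v0 * tau - g_mm * tau^2 / 2
  H[i] <- g$H0
  phase[i] <- "flight"

  i <- t >= Tb[4] & t < Tb[5]
  u <- (t[i] - Tb[4]) / p$t_landing
  cl <- g$c_land
  z[i] <- z_to - v0 * p$t_landing *
    (u - u^2 / 2 + cl * (u^2 / 2 - u^3 / 3))
  s <- pmin(1, pmax(0, (z_to - z[i]) / (B + E)))
  # heel lowers with smoothed landing progress: zero heel-drop rate at
  # touchdown (continuous with the frozen flight posture) and at the
  # landing squat
  s <- 3 * s^2 - 2 * s^3
  H[i] <- pmin(z[i] - g$z_ankle - E * (1 - s), g$H0)
  theta[i] <- p$spine_max_tilt_deg * p$landing_tilt_frac *
    minjerk(u) * pi / 180
  phase[i] <- "landing"

  i <- t >= Tb[5] & t < Tb[6]
  u <- (t[i] - Tb[5]) / p$t_standing
  a_land_end <- v0 * (1 + g$c_land) / p$t_landing
  z[i] <- qhermite(u, p$t_standing, g$z_up - B, 0, a_land_end, g$z_up, 0, 0)
  H[i] <- pmin(z[i] - g$z_ankle, g$H0)
  theta[i] <- p$spine_max_tilt_deg * p$landing_tilt_frac *
    (1 - minjerk(u)) * pi / 180
  phase[i] <- "standing"

  i <- t >= Tb[6]
  phase[i] <- "stand_post"

  if (any(H > g$H0 + 0.5) || any(H <= abs(g$Ls - g$Lt))) {
    abort("kinematically inconsistent profile: hip height leaves leg reach")
  }
  H <- pmin(H, g$H0)
  tibble::tibble(time_s = t, phase = phase, z = z, H = H,
                 theta = theta, phi = p$pelvis_tilt_ratio * theta)
}

# Sagittal (y anterior, z up) positions of joints, landmarks and the whole-
# body COM for a vector of times. Flight frames follow automatically: H is
# frozen and z is ballistic, so every point translates rigidly.
body_points <- function(p, t) {
  p <- validate_profile(p)
  g <- p$geom
  an <- p$anthro
  st <- profile_state(p, t)
  # leg geometry: hip above ankle, knee forward by the balance constraint
  cosa <- (g$Ls^2 + st$H^2 - g$Lt^2) / (2 * st$H * g$Ls)
  cosa <- pmin(1, pmax(-1, cosa))
  sina <- sqrt(pmax(0, 1 - cosa^2))
  z_a <- st$z - st$H
  pts <- list()
  pts$ankle <- cbind(y = rep(0, nrow(st)), z = z_a)
  pts$knee <- cbind(y = g$Ls * sina, z = z_a + g$Ls * cosa)
  pts$hip <- cbind(y = rep(0, nrow(st)), z = st$z)
  # foot: toe fixed during ground contact, rigid translation in flight
  z_off_flight <- ifelse(st$phase == "flight", st$z - (g$z_up + g$E), 0)
  toe_y <- 0.65 * an$foot_cm * 10
  pts$toe <- cbind(y = rep(toe_y, nrow(st)), z = 25 + z_off_flight)
  pts$heel <- cbind(y = rep(-0.25 * an$foot_cm * 10, nrow(st)),
                    z = 30 + (z_a - g$z_ankle))
  # pelvis landmarks: PSIS level with the hip centre; ASIS rotates with
  # pelvic tilt
  pw <- an$pelvic_width_cm * 10
  d_ant <- 0.35 * pw; d_up <- 0.48 * pw
  pts$psis <- cbind(y = rep(-40, nrow(st)), z = st$z)
  pts$asis <- cbind(y = d_ant * cos(st$phi) + d_up * sin(st$phi),
                    z = st$z - d_ant * sin(st$phi) + d_up * cos(st$phi))
  # trunk line
  sp <- an$spine_cm * 10
  dir_y <- sin(st$theta); dir_z <- cos(st$theta)
  pts$t10 <- cbind(y = 0.35 * sp * dir_y, z = st$z + 0.35 * sp * dir_z)
  pts$clav <- cbind(y = 0.85 * sp * dir_y, z = st$z + 0.85 * sp * dir_z)
  # whole-body COM from the segment-parameter table (both legs symmetric)
  seg <- segment_params(an)
  fr <- setNames(seg$mass_fraction, seg$segment)
  com_seg <- function(a, b, f) a + f * (b - a)
  foot_com <- com_seg(pts$heel, pts$toe, 0.5)
  shank_com <- com_seg(pts$knee, pts$ankle, 0.433)
  thigh_com <- com_seg(pts$hip, pts$knee, 0.433)
  hat_com <- cbind(y = 0.40 * sp * dir_y, z = st$z + 0.40 * sp * dir_z)
  pts$com <- 2 * (fr[["foot"]] * foot_com + fr[["shank"]] * shank_com +
                    fr[["thigh"]] * thigh_com) + fr[["hat"]] * hat_com
  attr(pts, "state") <- st
  pts
}

# second derivative with one-sided copies at the segment edges
second_diff <- function(x, dt) {
  n <- length(x)
  a <- numeric(n)
  if (n >= 3) {
    a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    a[1] <- a[2]; a[n] <- a[n - 1]
  }
  a
}

#' Generate a synthetic jump trial
#'
#' Evaluates the planar chain of a [jump_profile()] on the marker clock and,
#' independently, on the force-plate clock. Vertical GRF is computed from the
#' whole-body centre of mass, `F = m (a_com + g)`, split equally over two
#' plates (one per foot); it is exactly zero on flight frames. Gaussian noise
#' is then added at the profile's SDs. The returned trial carries the
#' construction ground truth in `$truth` (event frames on the marker clock,
#' takeoff velocity, apex rise).
#'
#' @param profile A [jump_profile()].
#' @param seed Integer seed; identical seeds give bit-identical trials.
#' @param subject_id,age_group,stage Labels attached to the trial.
#' @return A [jump_trial()].
#' @examples
#' trial <- generate_trial(jump_profile(t_flight = 0.4), seed = 1)
#' trial
#' @export
generate_trial <- function(profile, seed = NULL, subject_id = "SYN01",
                           age_group = 4L, stage = "unknown") {
  if (!is.null(seed)) set.seed(seed)
  p <- validate_profile(profile)
  validate_dynamics(p)
  g <- p$geom
  an <- p$anthro
  Tb <- profile_times(p)
  dt_m <- 1 / p$rate_markers
  t_m <- seq(0, Tb[7], by = dt_m)
  pts <- body_points(p, t_m)
  st <- attr(pts, "state")

  lat <- c(ASI = an$pelvic_width_cm * 5, PSI = 60,
           GT = an$pelvic_width_cm * 5 + 20, KNE = an$knee_width_cm * 5,
           ANK = an$ankle_width_cm * 5, TOE = 55, HEE = 55)
  mk <- tibble::tibble(time_s = t_m)
  put <- function(mk, label, yz, x) {
    mk[[paste0(label, "_X")]] <- rep(x, nrow(yz))
    mk[[paste0(label, "_Y")]] <- yz[, "y"]
    mk[[paste0(label, "_Z")]] <- yz[, "z"]
    mk
  }
  for (side in c("L", "R")) {
    sg <- if (side == "L") -1 else 1
    mk <- put(mk, paste0(side, "ASI"), pts$asis, sg * lat[["ASI"]])
    mk <- put(mk, paste0(side, "PSI"), pts$psis, sg * lat[["PSI"]])
    mk <- put(mk, paste0(side, "GT"), pts$hip, sg * lat[["GT"]])
    mk <- put(mk, paste0(side, "KNE"), pts$knee, sg * lat[["KNE"]])
    mk <- put(mk, paste0(side, "ANK"), pts$ankle, sg * lat[["ANK"]])
    mk <- put(mk, paste0(side, "TOE"), pts$toe, sg * lat[["TOE"]])
    mk <- put(mk, paste0(side, "HEE"), pts$heel, sg * lat[["HEE"]])
  }
  mk <- put(mk, "CLAV", pts$clav, 0)
  mk <- put(mk, "T10", pts$t10, 0)

  # force plates on their own clock, from the same closed-form trajectories
  dt_g <- 1 / p$rate_grf
  t_g <- seq(0, Tb[7], by = dt_g)
  pg <- body_points(p, t_g)
  stg <- attr(pg, "state")
  in_flight <- stg$phase == "flight"
  mass <- an$mass_kg
  fz <- numeric(length(t_g))
  fy <- numeric(length(t_g))
  for (seg_idx in split(seq_along(t_g)[!in_flight],
                        cumsum(c(1, diff(which(!in_flight)) > 1)))) {
    az <- second_diff(pg$com[seg_idx, "z"], dt_g) / 1000
    ay <- second_diff(pg$com[seg_idx, "y"], dt_g) / 1000
    fz[seg_idx] <- mass * (az + G_MS2)
    fy[seg_idx] <- mass * ay
  }
  if (any(fz[!in_flight] <= 0)) {
    abort("kinematically inconsistent profile: stance GRF would be negative")
  }
  # centre of pressure: under the COM projection while the foot is flat,
  # migrating to the forefoot as the heel rises (the contact area shrinks
  # to the metatarsal heads)
  e_heel <- (stg$z - stg$H) - g$z_ankle -
    ifelse(stg$phase == "flight", stg$z - (g$z_up + g$E), 0)
  blend <- if (g$E > 0) pmin(1, pmax(0, e_heel / g$E)) else 0
  toe_y <- 0.65 * an$foot_cm * 10
  cop <- pg$com[, "y"] + blend * (toe_y - pg$com[, "y"])
  grf <- dplyr::bind_rows(lapply(1:2, function(pl) {
    tibble::tibble(time_s = t_g, plate = pl, fz = fz / 2, fy = fy / 2,
                   cop_y = cop)
  }))
  grf <- dplyr::arrange(grf, .data$time_s, .data$plate)

  # measurement noise
  if (p$marker_noise_sd_mm > 0) {
    for (cl in setdiff(names(mk), "time_s")) {
      mk[[cl]] <- mk[[cl]] + stats::rnorm(nrow(mk), 0, p$marker_noise_sd_mm)
    }
  }
  if (p$grf_noise_sd_n > 0) {
    grf$fz <- grf$fz + stats::rnorm(nrow(grf), 0, p$grf_noise_sd_n)
  }

  frame_at <- function(tt) as.integer(round(tt / dt_m)) + 1L
  truth <- list(
    events = c(upright_start = frame_at(Tb[1]), max_squat = frame_at(Tb[2]),
               takeoff = frame_at(Tb[3]), touchdown = frame_at(Tb[4]),
               max_landing_squat = frame_at(Tb[5]),
               upright_end = frame_at(Tb[6])),
    v0_mm_s = g$v0, apex_rise_mm = g$v0^2 / (2000 * G_MS2),
    extension_mm = g$E, z_upright_mm = g$z_up,
    knee_included_upright_deg = g$knee_fun(g$H0) * 180 / pi,
    knee_included_squat_deg = g$knee_fun(g$H_sq) * 180 / pi,
    profile = p)
  jump_trial(mk, grf, an, subject_id = subject_id, age_group = age_group,
             stage = stage, truth = truth)
}

#' Solve a jump profile that realizes metric targets
#'
#' Inverts the generator geometry so that a trial produced from the returned
#' profile reproduces requested jump metrics. Supported targets:
#' `knee_rom_pushing_deg` (closed form via the two-link knee angle),
#' `flight_height_mm` (ballistic closed form), `spine_max_tilt_deg` (direct),
#' `hip_max_angvel_pushing_rad_s` (pushing duration, solved numerically) and
#' `ankle_rom_landing_deg` (buffer depth, solved numerically).
#'
#' @param targets Named list or named numeric vector of target values.
#' @param base Profile supplying every non-targeted parameter.
#' @return A [jump_profile()].
#' @examples
#' pr <- solve_profile(list(knee_rom_pushing_deg = 70.315))
#' @export
solve_profile <- function(targets, base = jump_profile()) {
  p <- validate_profile(base)
  g <- p$geom
  targets <- as.list(targets)
  known <- c("knee_rom_pushing_deg", "flight_height_mm", "spine_max_tilt_deg",
             "hip_max_angvel_pushing_rad_s", "ankle_rom_landing_deg")
  bad <- setdiff(names(targets), known)
  if (length(bad)) abort(paste0("unsupported profile targets: ",
                                paste(bad, collapse = ", ")))
  if (!is.null(targets$spine_max_tilt_deg)) {
    p$spine_max_tilt_deg <- targets$spine_max_tilt_deg
  }
  if (!is.null(targets$knee_rom_pushing_deg)) {
    # knee included angle: gamma(H); ROM over pushing = gamma(H0)-gamma(H_sq)
    gam0 <- g$knee_fun(g$H0)
    gam_sq <- gam0 - targets$knee_rom_pushing_deg * pi / 180
    if (gam_sq < 20 * pi / 180) abort("knee ROM target exceeds leg geometry")
    H_sq <- sqrt(g$Ls^2 + g$Lt^2 - 2 * g$Ls * g$Lt * cos(gam_sq))
    p$squat_depth_mm <- g$H0 - H_sq
  }
  if (!is.null(targets$flight_height_mm)) {
    h_ball <- targets$flight_height_mm - g$E
    if (h_ball <= 0) abort("flight height target below the takeoff extension")
    p$t_flight <- sqrt(8 * h_ball / (1000 * G_MS2))
  } else if (!is.null(targets$knee_rom_pushing_deg)) {
    # couple jump effort to squat depth: a shallow countermovement stores
    # less work, so the ballistic rise scales with the squat
    p$t_flight <- min(0.45, max(0.14, 0.30 * sqrt(p$squat_depth_mm / 150)))
  }
  # retie the dependent durations to the (possibly new) takeoff velocity
  v0_new <- 1000 * G_MS2 * p$t_flight / 2
  p$buffer_depth_mm <- min(p$buffer_depth_mm, 0.85 * p$squat_depth_mm + 20)
  p$t_pushing <- min(0.45, max(0.12,
    (p$squat_depth_mm + g$E) / (0.545 * v0_new)))
  p$t_landing <- (p$buffer_depth_mm + g$E) / (0.42 * v0_new)
  p <- validate_profile(p)
  if (!is.null(targets$ankle_rom_landing_deg)) {
    # the ankle's landing excursion is dominated by recovering the heel
    # raise (plantarflexed at touchdown, flat at the landing squat), so the
    # takeoff extension is the natural knob; the landing duration tracks the
    # total drop to keep the absorption profile mid-band
    land_t <- function(ext, bd) {
      (bd + ext * 0.5 * p$anthro$foot_cm * 10) / (0.42 * p$geom$v0)
    }
    f <- function(ext, bd = p$buffer_depth_mm) {
      q <- p; q$takeoff_extension <- ext; q$buffer_depth_mm <- bd
      q$t_landing <- land_t(ext, bd)
      measure_profile_metric(q, "ankle_rom_landing_deg") -
        targets$ankle_rom_landing_deg
    }
    if (f(0.05) > 0) {
      # even a flat-footed takeoff overshoots: absorb less deeply as well
      p$takeoff_extension <- 0.05
      fb <- function(bd) f(0.05, bd)
      if (fb(20) > 0) abort("ankle ROM landing target outside feasible range")
      p$buffer_depth_mm <- stats::uniroot(fb, c(20, p$buffer_depth_mm),
                                          tol = 1e-4)$root
    } else if (f(1) < 0) {
      # full heel raise still short of the target: deepen the buffer
      p$takeoff_extension <- 1
      fb <- function(bd) f(1, bd)
      if (fb(320) < 0) abort("ankle ROM landing target outside feasible range")
      p$buffer_depth_mm <- stats::uniroot(fb, c(p$buffer_depth_mm, 320),
                                          tol = 1e-4)$root
    } else {
      p$takeoff_extension <- stats::uniroot(f, c(0.05, 1), tol = 1e-4)$root
    }
    p$t_landing <- land_t(p$takeoff_extension, p$buffer_depth_mm)
    p <- validate_profile(p)
  }
  if (!is.null(targets$hip_max_angvel_pushing_rad_s)) {
    # faster hip drive needs a shorter push; when that would demand more
    # than 1 g of downward pelvis acceleration, recruit more pelvic tilt
    # (and, if the squat depth is not pinned by a knee target, a deeper
    # squat), as faster jumpers do
    solve_tp <- function(q) {
      f <- function(tp) {
        q$t_pushing <- tp
        measure_profile_metric(q, "hip_max_angvel_pushing_rad_s") -
          targets$hip_max_angvel_pushing_rad_s
      }
      stats::uniroot(f, c(0.08, 1.2), tol = 1e-5)$root
    }
    depth_free <- is.null(targets$knee_rom_pushing_deg)
    ok <- FALSE
    for (attempt in 0:6) {
      q <- p
      q$t_pushing <- tryCatch(solve_tp(q), error = function(e) NA)
      if (!is.na(q$t_pushing)) {
        feasible <- tryCatch({
          validate_dynamics(validate_profile(q)); TRUE
        }, error = function(e) FALSE)
        if (feasible) { p <- validate_profile(q); ok <- TRUE; break }
      }
      p$pelvis_tilt_ratio <- min(0.75, p$pelvis_tilt_ratio * 1.15)
      if (depth_free) p$squat_depth_mm <- min(p$squat_depth_mm * 1.1, 260)
      p <- validate_profile(p)
    }
    if (!ok) abort("hip angular velocity target outside the feasible range")
  }
  validate_dynamics(p)
  p
}

# Noise-free metric of a profile, measured through the same marker geometry
# the kinematics module sees (used by the profile solver).
measure_profile_metric <- function(p, metric) {
  p <- validate_profile(p)
  Tb <- profile_times(p)
  dt <- 1 / p$rate_markers
  # angle series are measured the way the pipeline measures them, i.e.
  # through the 10 Hz zero-phase marker filter, so solved targets are
  # reproduced by the full processing chain and not just by raw geometry
  if (metric == "hip_max_angvel_pushing_rad_s") {
    t <- seq(max(0, Tb[2] - 0.3), min(Tb[7], Tb[3] + 0.1), by = dt)
    pts <- body_points(p, t)
    hip <- projected_angle(cbind(0, pts$asis), cbind(0, pts$hip),
                           cbind(0, pts$knee))
    hip <- butter_zerophase(hip, 10, p$rate_markers)
    v <- central_diff(hip, dt) * pi / 180
    idx <- t >= Tb[2] & t < Tb[3]
    return(max(abs(v[idx])))
  }
  if (metric == "ankle_rom_landing_deg") {
    t <- seq(max(0, Tb[4] - 0.3), min(Tb[7], Tb[5] + 0.3), by = dt)
    pts <- body_points(p, t)
    # the impact makes the ankle swing fast enough that filtering markers
    # and filtering angles differ; emulate the pipeline exactly
    fl <- function(m) apply(m, 2, butter_zerophase, cutoff_hz = 10,
                            rate = p$rate_markers)
    ank <- projected_angle(cbind(0, fl(pts$knee)), cbind(0, fl(pts$ankle)),
                           cbind(0, fl(pts$toe)))
    idx <- t >= Tb[4] & t < Tb[5]
    return(max(ank[idx]) - min(ank[idx]))
  }
  if (metric == "knee_rom_pushing_deg") {
    g <- p$geom
    return((g$knee_fun(g$H0) - g$knee_fun(g$H_sq)) * 180 / pi)
  }
  if (metric == "spine_max_tilt_deg") return(p$spine_max_tilt_deg)
  if (metric == "flight_height_mm") {
    return(p$geom$E + 1000 * G_MS2 * p$t_flight^2 / 8)
  }
  abort(paste0("unknown metric: ", metric))
}

#' Group specifications for cohort simulation: stage effects
#'
#' Default per-stage metric distributions (mean, SD) for the metrics the
#' profile solver can realize: peak forward spine tilt, knee range of motion
#' in the pushing phase, ankle range of motion in the landing phase, and peak
#' hip angular velocity in the pushing phase.
#'
#' @return A long tibble with columns `stage`, `metric`, `mean`, `sd`.
#' @export
group_specs_stage <- function() {
  tibble::tribble(
    ~stage, ~metric, ~mean, ~sd,
    "initial", "spine_max_tilt_deg", 28.450, 5.591,
    "primary", "spine_max_tilt_deg", 33.693, 1.803,
    "mature", "spine_max_tilt_deg", 44.223, 3.210,
    "initial", "knee_rom_pushing_deg", 51.971, 7.514,
    "primary", "knee_rom_pushing_deg", 55.756, 2.617,
    "mature", "knee_rom_pushing_deg", 70.315, 4.601,
    "initial", "ankle_rom_landing_deg", 23.833, 3.523,
    "primary", "ankle_rom_landing_deg", 34.001, 1.218,
    "mature", "ankle_rom_landing_deg", 39.317, 2.157,
    "initial", "hip_max_angvel_pushing_rad_s", 7.526, 0.900,
    "primary", "hip_max_angvel_pushing_rad_s", 9.395, 0.311,
    "mature", "hip_max_angvel_pushing_rad_s", 10.463, 0.551
  )
}

#' Group specifications for cohort simulation: age effects
#'
#' Default per-age metric distributions. The printed SD of the 3-year-olds'
#' hip angular velocity (0.0520) is an order of magnitude below every
#' comparable dispersion and is treated as a typographical anomaly: the
#' default uses 0.52; pass `literal_sd = TRUE` for the value as printed.
#'
#' @param literal_sd Use the anomalous printed SD instead of the corrected one.
#' @return A long tibble with columns `age_group`, `metric`, `mean`, `sd`.
#' @export
group_specs_age <- function(literal_sd = FALSE) {
  out <- tibble::tribble(
    ~age_group, ~metric, ~mean, ~sd,
    3L, "ankle_rom_landing_deg", 26.573, 2.034,
    4L, "ankle_rom_landing_deg", 36.027, 2.012,
    5L, "ankle_rom_landing_deg", 39.634, 1.706,
    3L, "hip_max_angvel_pushing_rad_s", 8.140, 0.52,
    4L, "hip_max_angvel_pushing_rad_s", 9.232, 0.514,
    5L, "hip_max_angvel_pushing_rad_s", 10.946, 0.436
  )
  if (literal_sd) out$sd[out$age_group == 3L &
                           out$metric == "hip_max_angvel_pushing_rad_s"] <- 0.052
  out
}

#' Simulate a cohort of jump trials
#'
#' Draws per-subject metric targets from each group's Normal(mean, SD)
#' distribution -- truncated to mean +/- 4 SD intersected with physical
#' bounds -- solves each subject's [jump_profile()] to realize them, and
#' generates the trials. A subject whose targets remain infeasible after 100
#' redraws is skipped with a warning.
#'
#' @param specs Long tibble with columns `metric`, `mean`, `sd`, `n` and the
#'   group labels `age_group` and/or `stage` (see [group_specs_stage()],
#'   [group_specs_age()]); `n` is the subjects per group (recycled).
#' @param n_per_group Subjects per group when `specs` has no `n` column.
#' @param seed Integer seed.
#' @param base Base [jump_profile()] for non-targeted parameters.
#' @return A list of [jump_trial()] objects.
#' @export
sample_cohort <- function(specs, n_per_group = 10, seed = NULL,
                          base = jump_profile()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(specs) > 0)
  if (!"n" %in% names(specs)) specs$n <- n_per_group
  if (!"age_group" %in% names(specs)) specs$age_group <- 4L
  if (!"stage" %in% names(specs)) specs$stage <- "unknown"
  bounds <- list(knee_rom_pushing_deg = c(10, 120),
                 spine_max_tilt_deg = c(2, 80),
                 ankle_rom_landing_deg = c(5, 80),
                 hip_max_angvel_pushing_rad_s = c(2, 25),
                 flight_height_mm = c(30, 600))
  groups <- dplyr::group_split(dplyr::group_by(specs, .data$age_group,
                                               .data$stage))
  trials <- list()
  k <- 0L
  for (gspec in groups) {
    n <- gspec$n[1]
    for (s in seq_len(n)) {
      ok <- FALSE
      for (attempt in 1:100) {
        tg <- purrr::pmap(gspec[, c("metric", "mean", "sd")],
                          function(metric, mean, sd) {
          b <- bounds[[metric]]
          lo <- max(b[1], mean - 4 * sd); hi <- min(b[2], mean + 4 * sd)
          min(max(stats::rnorm(1, mean, sd), lo), hi)
        })
        names(tg) <- gspec$metric
        pr <- tryCatch(solve_profile(tg, base = base), error = function(e) NULL)
        if (!is.null(pr)) { ok <- TRUE; break }
      }
      if (!ok) {
        warn(sprintf("skipping infeasible subject in group %s/%s",
                     gspec$age_group[1], gspec$stage[1]))
        next
      }
      k <- k + 1L
      trials[[k]] <- generate_trial(
        pr, subject_id = sprintf("SYN%03d", k),
        age_group = gspec$age_group[1], stage = gspec$stage[1])
    }
  }
  trials
}

#' Flight-height regression coefficients
#'
#' The cohort-level linear model of flight height (mm) the package's
#' regression tooling is validated against: an intercept plus effects of
#' ankle pushing-phase range of motion (deg), peak spine tilt (deg), peak hip
#' angular velocity (rad/s), and the body-weight-normalized peak forces of
#' the gluteus minimus posterior and gastrocnemius medialis (N/BW).
#'
#' @return Tibble with columns `term` and `estimate`.
#' @export
flight_height_equation <- function() {
  tibble::tibble(
    term = c("(Intercept)", "ankle_rom_pushing_deg", "spine_max_tilt_deg",
             "hip_max_angvel_pushing_rad_s", "gmip_force_bw", "gm_force_bw"),
    estimate = c(-85.527, 1.243, 0.754, 9.354, 33.847, 2.640))
}

#' Evaluate the flight-height equation
#'
#' @param data Tibble with the five predictor columns named as in
#'   [flight_height_equation()].
#' @return Numeric vector of deterministic flight heights, mm.
#' @export
predict_flight_height <- function(data) {
  eq <- flight_height_equation()
  out <- rep(eq$estimate[1], nrow(data))
  for (i in 2:nrow(eq)) out <- out + eq$estimate[i] * data[[eq$term[i]]]
  out
}

#' Generate a cohort table for regression analysis
#'
#' Draws the five true predictors from distributions spanning the cohort
#' group means, adds uncorrelated decoy predictors, and sets the outcome to
#' the deterministic flight-height equation plus Gaussian noise. With
#' `noise_sd = NULL` the noise is calibrated analytically so the population
#' R^2 equals `r_squared`.
#'
#' @param n Number of subjects (>= 10).
#' @param noise_sd Residual SD in mm, or `NULL` to derive it from `r_squared`.
#' @param r_squared Population R^2 used when `noise_sd` is `NULL`.
#' @param seed Integer seed.
#' @param n_decoys Number of decoy predictors (named `decoy_1`, ...). The
#'   default of 3 keeps the chance that no decoy slips past a 0.05 entry
#'   threshold near `0.95^3 ~ 0.86`.
#' @return Tibble with predictors, decoys and `flight_height_mm`.
#' @export
generate_regression_cohort <- function(n, noise_sd = NULL, r_squared = 0.64,
                                       seed = NULL, n_decoys = 3) {
  if (n < 10) abort("n must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  spec <- tibble::tribble(
    ~term, ~mean, ~sd,
    "ankle_rom_pushing_deg", 35, 6,
    "spine_max_tilt_deg", 35, 6,
    "hip_max_angvel_pushing_rad_s", 9.5, 1.2,
    "gmip_force_bw", 1.0, 0.30,
    "gm_force_bw", 6.0, 1.5)
  out <- tibble::as_tibble(
    purrr::map(setNames(seq_len(nrow(spec)), spec$term), function(i) {
      pmax(stats::rnorm(n, spec$mean[i], spec$sd[i]), 0.05 * spec$mean[i])
    }))
  for (j in seq_len(n_decoys)) {
    out[[paste0("decoy_", j)]] <- stats::rnorm(n, 10 * j, 3 * j)
  }
  if (is.null(noise_sd)) {
    eq <- flight_height_equation()
    sig_var <- sum((eq$estimate[-1] * spec$sd)^2)
    noise_sd <- sqrt(sig_var * (1 - r_squared) / r_squared)
  }
  out$flight_height_mm <- predict_flight_height(out) +
    stats::rnorm(n, 0, noise_sd)
  attr(out, "noise_sd") <- noise_sd
  out
}
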
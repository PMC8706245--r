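#' Sagittal-projected angle at a joint
#'
#' Angle, in degrees, between the rays `b -> a` and `b -> c` after projecting
#' all three points onto the lab sagittal (Y-Z) plane. This is how every
#' joint angle in the analysis is defined: the included angle between two
#' marker rays at the vertex marker, so full extension reads close to 180
#' degrees and deep flexion reads small.
#'
#' @param a,b,c 3-D points, either length-3 vectors or n x 3 matrices
#'   (columns X mediolateral, Y anterior, Z vertical); `b` is the vertex.
#' @return Angle(s) in degrees, in \[0, 180\].
#' @examples
#' projected_angle(c(0, 0, 1), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
projected_angle <- function(a, b, c) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  a <- as_m(a); b <- as_m(b); c <- as_m(c)
  u <- a[, 2:3, drop = FALSE] - b[, 2:3, drop = FALSE]
  v <- c[, 2:3, drop = FALSE] - b[, 2:3, drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-12) || any(nv < 1e-12)) {
    abort("degenerate joint angle: a projected ray has zero length")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Forward trunk tilt from the vertical
#'
#' Signed angle between the trunk line (T10 up to the clavicle midpoint),
#' projected on the sagittal plane, and the vertical axis. Forward lean
#' (clavicle anterior of T10) is positive.
#'
#' @param clav_mid,t10 3-D points (vectors or n x 3 matrices), mm.
#' @return Tilt in degrees, in \[-90, 90\] for upright-ish postures.
#' @export
spine_tilt <- function(clav_mid, t10) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  clav_mid <- as_m(clav_mid); t10 <- as_m(t10)
  v <- clav_mid[, 2:3, drop = FALSE] - t10[, 2:3, drop = FALSE]
  if (any(rowSums(v^2) < 1e-12)) {
    abort("degenerate trunk line: clavicle and T10 coincide")
  }
  atan2(v[, 1], v[, 2]) * 180 / pi
}

# central differences, one-sided at the ends (deg/s for angle input)
central_diff <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  if (n >= 3) {
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    v[1] <- (x[2] - x[1]) / dt
    v[n] <- (x[n] - x[n - 1]) / dt
  } else if (n == 2) {
    v[] <- (x[2] - x[1]) / dt
  }
  v
}

#' Sagittal joint angle series of a trial
#'
#' Computes the per-frame included angles (degrees): hip (ASIS - greater
#' trochanter - lateral femoral epicondyle, vertex at the trochanter), knee
#' (trochanter - epicondyle - malleolus), ankle (epicondyle - malleolus -
#' fifth metatarsal head) and the signed forward spine tilt, all projected on
#' the sagittal plane.
#'
#' @param markers Marker tibble (typically `trial$markers`, filtered).
#' @param side `"R"` (default) or `"L"` chain.
#' @return Tibble `time_s`, `hip_deg`, `knee_deg`, `ankle_deg`,
#'   `spine_tilt_deg`.
#' @export
joint_angles <- function(markers, side = c("R", "L")) {
  side <- match.arg(side)
  validate_markers(markers, required = c(
    paste0(side, c("ASI", "GT", "KNE", "ANK", "TOE")), "CLAV", "T10"))
  m <- function(lbl) marker_xyz(markers, lbl)
  asi <- m(paste0(side, "ASI")); gt <- m(paste0(side, "GT"))
  kne <- m(paste0(side, "KNE")); ank <- m(paste0(side, "ANK"))
  toe <- m(paste0(side, "TOE"))
  tibble::tibble(
    time_s = markers$time_s,
    hip_deg = projected_angle(asi, gt, kne),
    knee_deg = projected_angle(gt, kne, ank),
    ankle_deg = projected_angle(kne, ank, toe),
    spine_tilt_deg = spine_tilt(m("CLAV"), m("T10")))
}

check_interval <- function(interval, n, min_len = 1) {
  if (length(interval) != 2 || interval[1] < 1 || interval[2] > n + 1 ||
      interval[2] <= interval[1]) {
    abort("interval must be a valid non-empty half-open [start, end) range")
  }
  if (interval[2] - interval[1] < min_len) {
    abort(sprintf("interval has fewer than %d frames", min_len))
  }
  seq(interval[1], interval[2] - 1)
}

#' Range of motion of an angle series over a phase
#'
#' Maximum minus minimum of the flexion angle over a half-open frame
#' interval; always non-negative.
#'
#' @param angle_series Numeric vector of angles, deg.
#' @param interval Half-open frame interval `c(start, end)`, 1-based.
#' @return ROM in degrees.
#' @export
phase_rom <- function(angle_series, interval) {
  idx <- check_interval(interval, length(angle_series))
  max(angle_series[idx]) - min(angle_series[idx])
}

#' Peak angular velocity over a phase
#'
#' Largest absolute angular velocity over a half-open frame interval, from
#' central differences of the (already filtered) angle series.
#'
#' @param angle_series Numeric vector of angles, deg.
#' @param interval Half-open frame interval `c(start, end)`, 1-based; at
#'   least 3 frames.
#' @param rate Sampling rate, Hz.
#' @return Peak |angular velocity| in rad/s.
#' @export
max_angular_velocity <- function(angle_series, interval, rate) {
  idx <- check_interval(interval, length(angle_series), min_len = 3)
  v <- central_diff(angle_series, 1 / rate)
  max(abs(v[idx])) * pi / 180
}

psis_midpoint_z <- function(markers) {
  (marker_xyz(markers, "LPSI")[, 3] + marker_xyz(markers, "RPSI")[, 3]) / 2
}

#' Spatiotemporal and joint metrics of one segmented trial
#'
#' Computes the full per-trial metric row: the five phase times and their
#' total; squat depth, flight height and landing buffer depth (vertical
#' excursions of the PSIS midpoint relative to its quiet-standing level, mm);
#' peak flexion angles (the smallest included angle, deg) for hip, knee and
#' ankle and the peak forward spine tilt; per-joint range of motion in the
#' compression, pushing and landing phases; and per-joint peak angular
#' velocity in the pushing phase (rad/s).
#'
#' @param trial A [jump_trial()] (markers assumed filtered as desired).
#' @param phases A [segment_phases()] result for this trial.
#' @param side Body side for the joint chain.
#' @return A one-row tibble.
#' @export
jump_metrics <- function(trial, phases, side = "R") {
  stopifnot(inherits(trial, "jump_trial"), inherits(phases, "jump_phases"))
  mk <- trial$markers
  rate <- series_rate(mk)
  ja <- joint_angles(mk, side = side)
  ev <- phases$events
  iv <- function(ph) {
    r <- phases$phases[phases$phases$phase == ph, ]
    c(r$start, r$end)
  }
  psis <- psis_midpoint_z(mk)
  ref <- mean(psis[phases$upright_window])
  span <- seq(ev[["upright_start"]], min(ev[["upright_end"]], length(psis)))
  phase_time <- function(ph) { i <- iv(ph); (i[2] - i[1]) / rate }

  # ROM and angular velocity use closed intervals: each phase runs from one
  # delimiting posture to the next, and the extreme at the closing boundary
  # (e.g. the maximum squat itself) belongs to the phase's excursion
  ivc <- function(ph) {
    i <- iv(ph)
    c(i[1], min(i[2] + 1, nrow(mk) + 1))
  }
  roms <- purrr::map(c(compression = "compression", pushing = "pushing",
                       landing = "landing"), ivc)
  joint_cols <- list(hip = ja$hip_deg, knee = ja$knee_deg,
                     ankle = ja$ankle_deg)
  rom_tbl <- purrr::imap(roms, function(intv, ph) {
    purrr::map(joint_cols, phase_rom, interval = intv)
  })
  flight_iv <- iv("flight")
  out <- tibble::tibble(
    compression_time_s = phase_time("compression"),
    pushing_time_s = phase_time("pushing"),
    flight_time_s = phase_time("flight"),
    landing_time_s = phase_time("landing"),
    standing_time_s = phase_time("standing"),
    total_time_s = (ev[["upright_end"]] - ev[["upright_start"]]) / rate,
    squat_depth_mm = ref - psis[ev[["max_squat"]]],
    flight_height_mm =
      max(psis[seq(flight_iv[1], flight_iv[2] - 1)]) - ref,
    buffer_depth_mm = ref - psis[ev[["max_landing_squat"]]],
    hip_max_flexion_deg = min(ja$hip_deg[span]),
    knee_max_flexion_deg = min(ja$knee_deg[span]),
    ankle_max_flexion_deg = min(ja$ankle_deg[span]),
    spine_max_tilt_deg = max(ja$spine_tilt_deg[span]))
  for (ph in names(roms)) {
    for (j in names(joint_cols)) {
      out[[paste0(j, "_rom_", ph, "_deg")]] <- rom_tbl[[ph]][[j]]
    }
  }
  push_iv <- ivc("pushing")
  for (j in names(joint_cols)) {
    out[[paste0(j, "_max_angvel_pushing_rad_s")]] <-
      max_angular_velocity(joint_cols[[j]], push_iv, rate)
  }
  out
}

#' Metric table for a list of trials
#'
#' Runs the default processing chain (marker and GRF filtering,
#' synchronization, segmentation, [jump_metrics()]) over a list of trials
#' and binds the rows into a cohort table with the group labels.
#'
#' @param trials List of [jump_trial()] objects.
#' @param marker_cutoff_hz,grf_cutoff_hz Filter cut-offs (10 and 20 Hz).
#' @param ... Passed to [segment_trial()].
#' @return Tibble, one row per trial, with `subject_id`, `age_group`,
#'   `stage` and all metric columns.
#' @export
cohort_metrics <- function(trials, marker_cutoff_hz = 10,
                           grf_cutoff_hz = 20, ...) {
  purrr::map_dfr(trials, function(tr) {
    proc <- preprocess_trial(tr, marker_cutoff_hz, grf_cutoff_hz)
    ph <- segment_trial(proc, ...)
    dplyr::bind_cols(
      tibble::tibble(subject_id = tr$subject_id,
                     age_group = tr$age_group, stage = tr$stage),
      jump_metrics(proc, ph))
  })
}

#' Filter and synchronize a trial in place
#'
#' Applies the conventional smoothing (markers at 10 Hz, GRF at 20 Hz, both
#' zero-phase) and resamples the GRF onto the marker clock.
#'
#' @param trial A [jump_trial()].
#' @param marker_cutoff_hz,grf_cutoff_hz Low-pass cut-offs; `NULL` skips
#'   that filter.
#' @param antialias Passed to [synchronize()].
#' @return A new [jump_trial()] with processed channels.
#' @export
preprocess_trial <- function(trial, marker_cutoff_hz = 10,
                             grf_cutoff_hz = 20, antialias = TRUE) {
  stopifnot(inherits(trial, "jump_trial"))
  mk <- trial$markers
  if (!is.null(marker_cutoff_hz)) mk <- lowpass_filter(mk, marker_cutoff_hz)
  grf <- trial$grf
  if (!is.null(grf_cutoff_hz)) grf <- lowpass_filter(grf, grf_cutoff_hz)
  sync <- synchronize(mk, grf, antialias = antialias)
  out <- trial
  out$markers <- sync$markers
  out$grf <- sync$grf
  out
}
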
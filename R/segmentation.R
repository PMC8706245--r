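#' Detect takeoff and touchdown from the vertical GRF
#'
#' Takeoff is the first frame at which the summed vertical GRF falls below
#' `threshold_n`; touchdown is the first subsequent frame at which it rises
#' back above. The default threshold of 10 N is roughly 5 percent of a 20 kg
#' child's weight, comfortably above a force plate's noise floor. If several
#' unloaded intervals are found the longest is used and a warning is issued.
#'
#' @param grf_vertical Numeric vector: summed vertical GRF per frame, on the
#'   marker clock (see [total_vertical_grf()]).
#' @param threshold_n Flight threshold, N.
#' @param debounce_frames Loaded gaps inside an unloaded interval up to this
#'   length are treated as noise and closed (default 2).
#' @return Named integer vector `c(takeoff =, touchdown =)`, 1-based frames.
#' @export
detect_ground_events <- function(grf_vertical, threshold_n = 10,
                                 debounce_frames = 2) {
  below <- grf_vertical < threshold_n
  # debounce: close short loaded gaps caused by noise spikes
  r0 <- rle(below)
  if (length(r0$lengths) > 2) {
    inner <- seq(2, length(r0$lengths) - 1)
    r0$values[inner][!r0$values[inner] &
                       r0$lengths[inner] <= debounce_frames] <- TRUE
  }
  below <- inverse.rle(r0)
  # unloaded runs bounded by stance on both sides
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & starts > 1 & ends < length(below))
  if (length(cand) == 0) abort("no flight detected")
  if (length(cand) > 1) {
    warn(sprintf("%d unloaded intervals found; using the longest",
                 length(cand)))
    cand <- cand[which.max(r$lengths[cand])]
  }
  c(takeoff = as.integer(starts[cand]),
    touchdown = as.integer(ends[cand] + 1L))
}

# quiet-standing runs: knee near its initial value and PSIS nearly still
quiet_runs <- function(knee_angle, psis_height, rate,
                       knee_tol_deg = 5, speed_tol_mm_s = 20,
                       min_dur_s = 0.1) {
  # heavy smoothing before differencing: stillness is a low-frequency
  # judgement and marker noise would otherwise swamp the speed threshold
  psis_height <- butter_zerophase(psis_height, 4, rate)
  speed <- abs(central_diff(psis_height, 1 / rate))
  still <- abs(knee_angle - knee_angle[1]) < knee_tol_deg &
    speed < speed_tol_mm_s
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_dur_s * rate
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# refine the frame of a local minimum by fitting a parabola over a window
# around the raw argmin and taking its (rounded) vertex; averaging over the
# window suppresses the frame jitter a noisy pointwise argmin would have
refine_argmin <- function(x, raw, half_window = 10, max_shift = 3) {
  lo <- max(1, raw - half_window); hi <- min(length(x), raw + half_window)
  if (hi - lo < 6) return(raw)
  k <- seq(lo, hi) - raw
  # cubic rather than quadratic: the trajectory's curvature differs on the
  # two sides of the reversal, and the cubic term absorbs that asymmetry
  cf <- stats::lm.fit(cbind(1, k, k^2, k^3), x[seq(lo, hi)])$coefficients
  disc <- cf[3]^2 - 3 * cf[4] * cf[2]
  if (!is.finite(disc) || disc < 0) return(raw)
  roots <- (-cf[3] + c(1, -1) * sqrt(disc)) / (3 * cf[4])
  vertex <- roots[which.min(abs(roots))]
  if (!is.finite(vertex)) return(raw)
  raw + as.integer(round(max(-max_shift, min(max_shift, vertex))))
}

# first frame of a sustained (>= min_run frames) threshold exceedance at or
# after `from`; NA if none
first_sustained <- function(flag, from, min_run = 3) {
  n <- length(flag)
  if (from > n) return(NA_integer_)
  idx <- from:n
  r <- rle(flag[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_integer_)
  as.integer(idx[starts[hit[1]]])
}

#' Segment a jump into its five phases
#'
#' Splits a synchronized trial into compression, pushing, flight, landing
#' and standing, as half-open frame intervals on the marker clock, plus the
#' six delimiting events. Takeoff and touchdown come from the GRF flight
#' threshold; the squat extrema are the frames of maximum knee flexion
#' (smallest included angle, earliest on ties) before takeoff and after
#' touchdown. The upright boundaries are located in two steps: quiet
#' standing is found where the knee angle stays within `knee_tol_deg` of its
#' initial value and the PSIS midpoint moves slower than `speed_tol_mm_s`
#' for at least 0.1 s; the movement onset/offset is then sharpened to the
#' frame where the GRF starts (stops) deviating from body weight by more
#' than `onset_dev_n`, since the force signal responds to acceleration and
#' therefore turns one differentiation earlier than any position channel.
#'
#' @param knee_angle_series Included knee angle per frame, deg.
#' @param grf_vertical Summed vertical GRF per frame, N (marker clock).
#' @param psis_height PSIS-midpoint height per frame, mm.
#' @param rate Sampling rate, Hz.
#' @param threshold_n Flight-detection threshold, N.
#' @param onset_dev_n Deviation from body weight marking movement, N;
#'   `NULL` (default) adapts to the quiet-stance noise as
#'   `max(6, 5 * mad)`.
#' @param knee_tol_deg,speed_tol_mm_s Quiet-standing tolerances.
#' @return An object of class `jump_phases`: list with `events` (named
#'   frames), `phases` (tibble `phase`, `start`, `end`), `upright_window`
#'   (frames used as the upright reference), `bodyweight_n` and `flags`.
#' @export
segment_phases <- function(knee_angle_series, grf_vertical, psis_height,
                           rate = 100, threshold_n = 10, onset_dev_n = NULL,
                           knee_tol_deg = 5, speed_tol_mm_s = 20) {
  n <- length(knee_angle_series)
  stopifnot(length(grf_vertical) == n, length(psis_height) == n)
  ev_gr <- detect_ground_events(grf_vertical, threshold_n)
  takeoff <- ev_gr[["takeoff"]]; touchdown <- ev_gr[["touchdown"]]

  pre <- knee_angle_series[1:(takeoff - 1)]
  if (max(pre) - min(pre) < 5) {
    abort("no squat detected: knee flexion has no extremum before takeoff")
  }
  max_squat <- refine_argmin(knee_angle_series, which.min(pre))
  post <- knee_angle_series[touchdown:n]
  max_landing_squat <- refine_argmin(knee_angle_series,
                                     touchdown - 1L + which.min(post))

  qr <- quiet_runs(knee_angle_series, psis_height, rate,
                   knee_tol_deg, speed_tol_mm_s)
  flags <- character(0)
  pre_runs <- qr[qr$end < max_squat, ]
  if (nrow(pre_runs) == 0) {
    abort("no pre-jump quiet standing found")
  }
  upright_window <- seq(pre_runs$start[nrow(pre_runs)],
                        pre_runs$end[nrow(pre_runs)])
  # robust body weight and noise scale: the detected quiet run can bleed a
  # few frames into the movement, so median/MAD rather than mean/sd
  bw <- median(grf_vertical[upright_window])
  if (is.null(onset_dev_n)) {
    # adaptive movement threshold: 5 sigma of the quiet-stance force noise,
    # never below 6 N
    onset_dev_n <- max(6, 5 * stats::mad(grf_vertical[upright_window]))
  }

  dev <- abs(grf_vertical - bw) > onset_dev_n
  onset <- first_sustained(dev, from = upright_window[1])
  upright_start <- if (is.na(onset) || onset >= max_squat) {
    flags <- c(flags, "onset_fallback")
    upright_window[length(upright_window)]
  } else as.integer(onset - 1L)
  # the upright reference must not include movement frames
  upright_window <- upright_window[upright_window <= upright_start]

  post_runs <- qr[qr$start > max_landing_squat, ]
  if (nrow(post_runs) == 0) {
    flags <- c(flags, "no_standing_recovery")
    upright_end <- max_landing_squat
  } else {
    pw <- seq(post_runs$start[1], post_runs$end[1])
    # offset: last sustained deviation from body weight before the quiet run
    devr <- rev(dev[1:pw[length(pw)]])
    off <- first_sustained(devr, from = 1)
    upright_end <- if (is.na(off)) {
      flags <- c(flags, "offset_fallback")
      as.integer(pw[1])
    } else as.integer(pw[length(pw)] - off + 2L)
    if (upright_end <= max_landing_squat) upright_end <- as.integer(pw[1])
  }

  events <- c(upright_start = as.integer(upright_start),
              max_squat = as.integer(max_squat),
              takeoff = as.integer(takeoff),
              touchdown = as.integer(touchdown),
              max_landing_squat = as.integer(max_landing_squat),
              upright_end = as.integer(upright_end))
  if (any(diff(events) < 0)) abort("inconsistent event ordering")
  phases <- tibble::tibble(
    phase = c("compression", "pushing", "flight", "landing", "standing"),
    start = unname(events[-6]), end = unname(events[-1]))
  structure(list(events = events, phases = phases,
                 upright_window = upright_window, bodyweight_n = bw,
                 flags = flags),
            class = "jump_phases")
}

#' @export
print.jump_phases <- function(x, ...) {
  cat("<jump_phases>\n")
  print(x$phases)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Segment a preprocessed trial
#'
#' Convenience wrapper: computes the knee angle series, summed vertical GRF
#' and PSIS-midpoint height from a (synchronized) trial and calls
#' [segment_phases()].
#'
#' @param trial A [jump_trial()] whose GRF is on the marker clock (see
#'   [preprocess_trial()]).
#' @param side Chain side for the knee angle.
#' @param ... Passed to [segment_phases()].
#' @return A `jump_phases` object.
#' @export
segment_trial <- function(trial, side = "R", ...) {
  stopifnot(inherits(trial, "jump_trial"))
  ja <- joint_angles(trial$markers, side = side)
  fz <- total_vertical_grf(trial$grf)
  if (nrow(fz) != nrow(trial$markers)) {
    abort("GRF is not on the marker clock; run preprocess_trial() first")
  }
  segment_phases(ja$knee_deg, fz$fz_total, psis_midpoint_z(trial$markers),
                 rate = series_rate(trial$markers), ...)
}

#' Classify the developmental stage of a jump
#'
#' Applies the qualitative motor-development criteria as quantitative rules:
#' a jump without a two-foot takeoff is `initial`; a two-foot jump whose knee
#' crouch angle (included knee angle at maximum squat) lies in \[60, 90\]
#' degrees with the body fully extended at takeoff is `mature`; every other
#' two-foot jump is `primary`. The function is total: every admissible input
#' maps to exactly one label.
#'
#' @param knee_crouch_angle_deg Included knee angle at maximum squat, in
#'   (0, 180) degrees. Vectorized.
#' @param extension_at_takeoff Logical: body fully extended at takeoff.
#' @param two_foot_takeoff Logical: both feet left the ground together.
#' @return Tibble with `stage` (factor initial/primary/mature) and the three
#'   pieces of supporting evidence.
#' @examples
#' classify_stage(75, TRUE, TRUE)    # mature
#' classify_stage(110, FALSE, TRUE)  # primary
#' classify_stage(110, FALSE, FALSE) # initial
#' @export
classify_stage <- function(knee_crouch_angle_deg, extension_at_takeoff,
                           two_foot_takeoff) {
  k <- length(knee_crouch_angle_deg)
  stopifnot(all(knee_crouch_angle_deg > 0 & knee_crouch_angle_deg < 180))
  extension_at_takeoff <- rep_len(extension_at_takeoff, k)
  two_foot_takeoff <- rep_len(two_foot_takeoff, k)
  stage <- ifelse(!two_foot_takeoff, "initial",
                  ifelse(knee_crouch_angle_deg >= 60 &
                           knee_crouch_angle_deg <= 90 &
                           extension_at_takeoff, "mature", "primary"))
  tibble::tibble(
    stage = factor(stage, levels = c("initial", "primary", "mature")),
    knee_crouch_angle_deg = knee_crouch_angle_deg,
    extension_at_takeoff = extension_at_takeoff,
    two_foot_takeoff = two_foot_takeoff)
}

#' Stage classification from a segmented trial
#'
#' Derives the three classifier inputs from the data: the crouch angle is
#' the included knee angle at maximum squat; "fully extended at takeoff"
#' means the hip and knee included angles at the takeoff frame are within
#' `extension_tol_deg` of their quiet-standing values (the hip's included
#' marker angle reads well below 180 even in neutral posture, so upright
#' stance is the meaningful extension reference); "two-foot takeoff" means
#' the per-plate takeoff frames agree within `two_foot_tol_frames`.
#'
#' @param trial Preprocessed [jump_trial()].
#' @param phases Its [segment_phases()] result.
#' @param extension_tol_deg Extension tolerance (default 20 deg).
#' @param two_foot_tol_frames Plate agreement tolerance (default 3 frames).
#' @param threshold_n Per-plate flight threshold, N.
#' @return One-row tibble as in [classify_stage()].
#' @export
stage_from_trial <- function(trial, phases, extension_tol_deg = 20,
                             two_foot_tol_frames = 3, threshold_n = 5) {
  ja <- joint_angles(trial$markers)
  ev <- phases$events
  crouch <- ja$knee_deg[ev[["max_squat"]]]
  to <- ev[["takeoff"]]
  hip_up <- mean(ja$hip_deg[phases$upright_window])
  knee_up <- mean(ja$knee_deg[phases$upright_window])
  extended <- abs(ja$hip_deg[to] - hip_up) < extension_tol_deg &&
    ja$knee_deg[to] > knee_up - extension_tol_deg
  per_plate <- vapply(split(trial$grf, trial$grf$plate), function(p) {
    ev_p <- tryCatch(detect_ground_events(p$fz, threshold_n),
                     error = function(e) c(takeoff = NA_integer_,
                                           touchdown = NA_integer_))
    ev_p[["takeoff"]]
  }, integer(1))
  two_foot <- !anyNA(per_plate) &&
    (max(per_plate) - min(per_plate)) <= two_foot_tol_frames
  classify_stage(crouch, extended, two_foot)
}
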
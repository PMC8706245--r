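#' Marker labels required by the sagittal jump analysis
#'
#' The lower-limb marker subset the pipeline consumes: anterior and posterior
#' superior iliac spines (both sides), the right-side chain greater trochanter,
#' lateral femoral epicondyle, lateral malleolus and fifth metatarsal head, and
#' the trunk markers (clavicle midpoint, T10). Additional Plug-in-Gait labels
#' (left-side chain, head, heels) are accepted in a trial but not required.
#'
#' @return Character vector of marker labels.
#' @export
required_markers <- function() {
  c("LASI", "RASI", "LPSI", "RPSI",
    "RGT", "RKNE", "RANK", "RTOE",
    "CLAV", "T10")
}

#' Subject anthropometrics
#'
#' Builds and validates the one-row table of morphological measurements used
#' for segment scaling and the synthetic generator. Any segment measure left
#' `NULL` is filled from stature using conventional segment-length fractions
#' (thigh 0.245 H, shank 0.246 H, foot 0.152 H, spine 0.30 H, pelvic width
#' 0.191 H, knee width 0.08 H, ankle width 0.055 H).
#'
#' @param height_cm Stature in cm.
#' @param mass_kg Body mass in kg.
#' @param thigh_cm,shank_cm,spine_cm,foot_cm Segment lengths in cm.
#' @param pelvic_width_cm,knee_width_cm,ankle_width_cm Widths in cm.
#' @return A one-row tibble of class `anthropometrics`.
#' @examples
#' anthropometrics(109.1, 18.4)
#' @export
anthropometrics <- function(height_cm, mass_kg,
                            thigh_cm = NULL, shank_cm = NULL,
                            spine_cm = NULL, foot_cm = NULL,
                            pelvic_width_cm = NULL, knee_width_cm = NULL,
                            ankle_width_cm = NULL) {
  stopifnot(is.numeric(height_cm), is.numeric(mass_kg))
  out <- tibble::tibble(
    height_cm = height_cm,
    mass_kg = mass_kg,
    thigh_cm = thigh_cm %||% 0.245 * height_cm,
    shank_cm = shank_cm %||% 0.246 * height_cm,
    spine_cm = spine_cm %||% 0.300 * height_cm,
    foot_cm = foot_cm %||% 0.152 * height_cm,
    pelvic_width_cm = pelvic_width_cm %||% 0.191 * height_cm,
    knee_width_cm = knee_width_cm %||% 0.080 * height_cm,
    ankle_width_cm = ankle_width_cm %||% 0.055 * height_cm
  )
  if (any(unlist(out) <= 0)) {
    abort("all anthropometric measures must be strictly positive")
  }
  if (height_cm < 80 || height_cm > 140) {
    warn(sprintf("height %.1f cm is outside the expected child range [80, 140]",
                 height_cm))
  }
  if (mass_kg < 10 || mass_kg > 40) {
    warn(sprintf("mass %.1f kg is outside the expected child range [10, 40]",
                 mass_kg))
  }
  class(out) <- c("anthropometrics", class(out))
  out
}

marker_labels <- function(markers) {
  nm <- setdiff(names(markers), "time_s")
  unique(sub("_[XYZ]$", "", nm))
}

series_rate <- function(df) {
  dt <- diff(df$time_s)
  if (length(dt) == 0 || any(dt <= 0)) abort("time_s must be strictly increasing")
  1 / median(dt)
}

marker_xyz <- function(markers, label) {
  cols <- paste0(label, c("_X", "_Y", "_Z"))
  miss <- setdiff(cols, names(markers))
  if (length(miss)) abort(paste0("missing marker columns: ",
                                 paste(miss, collapse = ", ")))
  as.matrix(markers[, cols])
}

validate_markers <- function(markers, required = required_markers()) {
  if (!"time_s" %in% names(markers)) abort("markers must have a time_s column")
  have <- marker_labels(markers)
  absent <- setdiff(required, have)
  if (length(absent)) {
    abort(paste0("required markers absent: ", paste(absent, collapse = ", ")))
  }
  invisible(markers)
}

validate_grf <- function(grf) {
  need <- c("time_s", "plate", "fz")
  miss <- setdiff(need, names(grf))
  if (length(miss)) abort(paste0("GRF table lacks columns: ",
                                 paste(miss, collapse = ", ")))
  invisible(grf)
}

#' Assemble a jump trial
#'
#' A trial bundles the marker trajectories (wide tibble, mm), the force-plate
#' record (long tibble with one row per frame per plate, N), the subject's
#' anthropometrics, and the group labels used by the cohort statistics.
#'
#' @param markers Tibble with `time_s` plus `<LABEL>_X/_Y/_Z` columns in mm.
#'   Lab frame: +Z up, +Y the facing (anterior) direction, +X mediolateral.
#' @param grf Tibble with `time_s`, `plate`, `fz` (vertical, N) and optionally
#'   `fy` (anterior, N), `fx` (lateral, N) and `cop_y` (anterior centre of
#'   pressure, mm).
#' @param anthro An [anthropometrics()] row.
#' @param subject_id Identifier string.
#' @param age_group One of 3, 4, 5 (years).
#' @param stage Developmental stage label: `"initial"`, `"primary"`,
#'   `"mature"` or `"unknown"`.
#' @param truth Optional list of generator ground truth (kept by
#'   [generate_trial()]; `NULL` for measured data).
#' @return An object of class `jump_trial`.
#' @export
jump_trial <- function(markers, grf, anthro,
                       subject_id = "S01", age_group = 4L,
                       stage = "unknown", truth = NULL) {
  validate_markers(markers)
  validate_grf(grf)
  stopifnot(inherits(anthro, "anthropometrics"))
  if (!age_group %in% c(3L, 4L, 5L)) abort("age_group must be 3, 4 or 5")
  stage <- match.arg(stage, c("initial", "primary", "mature", "unknown"))
  if (max(markers$time_s) < min(grf$time_s) ||
      max(grf$time_s) < min(markers$time_s)) {
    abort("marker and GRF time spans do not overlap")
  }
  structure(
    list(subject_id = subject_id, age_group = as.integer(age_group),
         stage = stage, markers = tibble::as_tibble(markers),
         grf = tibble::as_tibble(grf), anthro = anthro, truth = truth),
    class = "jump_trial")
}

#' @export
print.jump_trial <- function(x, ...) {
  cat(sprintf("<jump_trial> subject %s, age group %d, stage %s\n",
              x$subject_id, x$age_group, x$stage))
  cat(sprintf("  markers: %d labels x %d frames @ %.0f Hz\n",
              length(marker_labels(x$markers)), nrow(x$markers),
              series_rate(x$markers)))
  np <- length(unique(x$grf$plate))
  cat(sprintf("  grf: %d plate(s) x %d frames @ %.0f Hz\n",
              np, nrow(x$grf) / np,
              series_rate(x$grf[x$grf$plate == x$grf$plate[1], ])))
  invisible(x)
}

#' Read a trial from disk
#'
#' Reads the package's plain-text trial layout: a directory holding
#' `markers.csv` (one row per frame, columns `time_s` then `<LABEL>_X/_Y/_Z`
#' in mm), `grf.csv` (`time_s`, `plate`, `fz`, optionally `fy`, `fx`,
#' `cop_y`), and `trial.yaml` (subject id, group labels, anthropometrics).
#' Marker gaps must be encoded as `NA`; they are flagged, never silently
#' interpolated here (see [fill_marker_gaps()]).
#'
#' @param path Directory containing the three files.
#' @param format Only `"csv"` is supported; `"c3d"` raises an error.
#' @return A [jump_trial()].
#' @seealso [write_trial()]
#' @export
read_trial <- function(path, format = c("csv", "c3d")) {
  format <- match.arg(format)
  if (format == "c3d") {
    abort("C3D input is not supported by this build; export the trial as CSV")
  }
  if (!dir.exists(path)) abort(paste0("no such trial directory: ", path))
  mfile <- file.path(path, "markers.csv")
  gfile <- file.path(path, "grf.csv")
  yfile <- file.path(path, "trial.yaml")
  for (f in c(mfile, gfile, yfile)) {
    if (!file.exists(f)) abort(paste0("trial file missing: ", f))
  }
  markers <- tibble::as_tibble(utils::read.csv(mfile, check.names = FALSE))
  grf <- tibble::as_tibble(utils::read.csv(gfile, check.names = FALSE))
  meta <- yaml::read_yaml(yfile)
  an <- do.call(anthropometrics, meta$anthropometrics)
  n_gap <- sum(is.na(markers[setdiff(names(markers), "time_s")]))
  if (n_gap > 0) {
    warn(sprintf("%d marker samples are gaps (NA); see fill_marker_gaps()",
                 n_gap))
  }
  jump_trial(markers, grf, an,
             subject_id = meta$subject_id %||% "S01",
             age_group = meta$age_group %||% 4L,
             stage = meta$stage %||% "unknown")
}

#' Write a trial to disk
#'
#' Inverse of [read_trial()]: writes `markers.csv`, `grf.csv` and
#' `trial.yaml` into `path`. Coordinates are written at full double
#' precision, so a round trip preserves them to well below 1e-9 mm.
#'
#' @param trial A [jump_trial()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "jump_trial"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$markers, file.path(path, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$grf, file.path(path, "grf.csv"), row.names = FALSE)
  meta <- list(subject_id = trial$subject_id,
               age_group = trial$age_group,
               stage = trial$stage,
               anthropometrics = as.list(trial$anthro))
  yaml::write_yaml(meta, file.path(path, "trial.yaml"))
  invisible(path)
}

#' Interpolate short marker gaps
#'
#' Cubic-spline interpolates runs of missing samples of length at most
#' `max_gap` frames, with a warning; a longer gap fails the trial, since a
#' spline over a long occlusion would fabricate movement.
#'
#' @param markers Marker tibble.
#' @param max_gap Longest run of missing frames to repair (default 10).
#' @return The repaired tibble.
#' @export
fill_marker_gaps <- function(markers, max_gap = 10) {
  cols <- setdiff(names(markers), "time_s")
  t <- markers$time_s
  filled <- 0L
  for (cl in cols) {
    x <- markers[[cl]]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    if (max(r$lengths[r$values]) > max_gap) {
      abort(sprintf("marker gap longer than %d frames in column %s",
                    max_gap, cl))
    }
    ok <- !is.na(x)
    markers[[cl]] <- stats::spline(t[ok], x[ok], xout = t)$y
    filled <- filled + sum(!ok)
  }
  if (filled > 0) warn(sprintf("interpolated %d gap samples", filled))
  markers
}

# Zero-phase Butterworth: forward-backward pass with odd-symmetric reflection
# padding at both ends (edge transients otherwise corrupt the first/last ~0.1 s).
butter_zerophase <- function(x, cutoff_hz, rate, order = 2) {
  if (cutoff_hz >= rate / 2) {
    abort(sprintf("cutoff %.1f Hz is at or above Nyquist (%.1f Hz)",
                  cutoff_hz, rate / 2))
  }
  n <- length(x)
  if (n < 8) return(x)
  # order here is per pass; two passes double the effective order
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  np <- min(n - 1, max(12, round(rate)))
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[seq(np + 1, np + n)]
}

#' Zero-phase low-pass filter
#'
#' Fourth-order (2 x 2nd order, forward-backward) Butterworth low-pass with
#' zero phase lag, the smoothing conventionally applied to gait data: 10 Hz
#' for marker trajectories and 20 Hz for force-plate channels. The
#' forward-backward application cancels phase lag and preserves the DC
#' component; reflection padding suppresses end transients.
#'
#' @param x A numeric vector, or a tibble whose numeric columns (other than
#'   `time_s`, `plate`, `frame`) are filtered column-wise. For GRF tables the
#'   filter is applied per plate.
#' @param cutoff_hz Cut-off frequency, Hz; must be below Nyquist.
#' @param rate Sampling rate, Hz. Inferred from `time_s` when `x` is a tibble.
#' @param order Order of each pass (default 2, i.e. 4th-order zero-phase).
#' @return Same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' noisy <- sin(2 * pi * t) + 0.5 * sin(2 * pi * 40 * t)
#' smooth <- lowpass_filter(noisy, 10, rate = 100)
#' @export
lowpass_filter <- function(x, cutoff_hz, rate = NULL, order = 2) {
  if (is.numeric(x)) {
    if (is.null(rate)) abort("rate is required for a bare numeric vector")
    return(butter_zerophase(x, cutoff_hz, rate, order))
  }
  stopifnot(is.data.frame(x))
  rate <- rate %||% if ("plate" %in% names(x)) {
    series_rate(x[x$plate == x$plate[1], ])
  } else {
    series_rate(x)
  }
  skip <- c("time_s", "plate", "frame")
  if ("plate" %in% names(x) && length(unique(x$plate)) > 1) {
    parts <- split(x, x$plate)
    out <- lapply(parts, function(p) {
      for (cl in setdiff(names(p), skip)) {
        if (is.numeric(p[[cl]])) {
          p[[cl]] <- butter_zerophase(p[[cl]], cutoff_hz, rate, order)
        }
      }
      p
    })
    out <- dplyr::bind_rows(out)
    return(dplyr::arrange(out, .data$time_s, .data$plate))
  }
  for (cl in setdiff(names(x), skip)) {
    if (is.numeric(x[[cl]])) {
      x[[cl]] <- butter_zerophase(x[[cl]], cutoff_hz, rate, order)
    }
  }
  x
}

#' Synchronize force-plate data onto the marker clock
#'
#' Resamples the (typically 250 Hz) GRF channels onto the (100 Hz) marker
#' time base by anti-aliased decimation: a zero-phase low-pass at 0.45 of the
#' target rate, then linear interpolation at the marker sample times over the
#' overlapping span. Kinematic events are defined on the marker clock, which
#' is why the GRF moves rather than the markers.
#'
#' @param markers Marker tibble (defines the target clock).
#' @param grf GRF tibble at its native rate.
#' @param antialias Apply the anti-alias low-pass before interpolation
#'   (default `TRUE`; set `FALSE` when the channels are already band-limited
#'   and exact step edges must be preserved, e.g. noise-free simulations).
#' @return A list with elements `markers` and `grf`, both restricted to the
#'   common span, plus attributes `span` (first/last common time).
#' @export
synchronize <- function(markers, grf, antialias = TRUE) {
  validate_grf(grf)
  rate_m <- series_rate(markers)
  t0 <- max(min(markers$time_s), min(grf$time_s))
  t1 <- min(max(markers$time_s), max(grf$time_s))
  if (t0 >= t1) abort("marker and GRF time spans do not overlap")
  keep <- markers$time_s >= t0 - 1e-9 & markers$time_s <= t1 + 1e-9
  mk <- markers[keep, ]
  tt <- mk$time_s
  plates <- split(grf, grf$plate)
  chans <- setdiff(names(grf), c("time_s", "plate"))
  out <- lapply(plates, function(p) {
    rate_g <- series_rate(p)
    res <- tibble::tibble(time_s = tt, plate = p$plate[1])
    for (cl in chans) {
      x <- p[[cl]]
      if (antialias && rate_g > rate_m) {
        x <- butter_zerophase(x, 0.45 * rate_m, rate_g)
      }
      res[[cl]] <- stats::approx(p$time_s, x, xout = tt, rule = 2)$y
    }
    res
  })
  grf_out <- dplyr::arrange(dplyr::bind_rows(out), .data$time_s, .data$plate)
  structure(list(markers = mk, grf = grf_out), span = c(t0, t1))
}

#' Summed vertical ground reaction force per frame
#'
#' @param grf Synchronized GRF tibble (possibly multiple plates).
#' @return Tibble with `time_s` and `fz_total`.
#' @export
total_vertical_grf <- function(grf) {
  validate_grf(grf)
  dplyr::summarise(dplyr::group_by(grf, .data$time_s),
                   fz_total = sum(.data$fz), .groups = "drop")
}
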
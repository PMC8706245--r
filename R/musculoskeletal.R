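# Segment mass / COM / gyration fractions for a young child, Winter-style
# conventions (mass as fraction of body mass per side, COM measured from the
# proximal joint, radius of gyration about the COM as fraction of segment
# length). "hat" is head + arms + trunk + pelvis, hung above the hip.
SEGMENT_TABLE <- tibble::tibble(
  segment = c("foot", "shank", "thigh", "hat"),
  mass_fraction = c(0.019, 0.045, 0.105, 0.662),
  com_fraction = c(0.50, 0.433, 0.433, 0.400),
  gyration_fraction = c(0.475, 0.302, 0.323, 0.500)
)

#' Scale body-segment parameters from anthropometrics
#'
#' Multiplies the documented child segment-mass fractions by body mass and
#' attaches the measured segment lengths, centre-of-mass position fractions
#' and radii of gyration used by the inverse dynamics and the synthetic
#' generator. Fractions are per side for foot, shank and thigh; `hat`
#' (head-arms-trunk incl. pelvis) is the remainder.
#'
#' @param anthro An [anthropometrics()] row.
#' @return Tibble: `segment`, `mass_fraction`, `mass_kg`, `length_m`,
#'   `com_fraction`, `gyration_fraction`.
#' @examples
#' segment_params(anthropometrics(109.1, 18.4))
#' @export
segment_params <- function(anthro) {
  stopifnot(inherits(anthro, "anthropometrics"))
  out <- SEGMENT_TABLE
  out$mass_kg <- out$mass_fraction * anthro$mass_kg
  out$length_m <- c(anthro$foot_cm, anthro$shank_cm, anthro$thigh_cm,
                    anthro$spine_cm) / 100
  out[, c("segment", "mass_fraction", "mass_kg", "length_m",
          "com_fraction", "gyration_fraction")]
}

# planar cross product r x F with r=(y,z) in m, F=(Fy,Fz) in N -> moment
# about the mediolateral axis (N.m), positive counterclockwise when the
# subject faces +Y
cross2 <- function(ry, rz, fy, fz) ry * fz - rz * fy

#' Planar link-segment inverse dynamics
#'
#' Bottom-up Newton-Euler over the sagittal plane for one leg: net internal
#' joint moments at the ankle (from the foot and the plate force applied at
#' the centre of pressure), the knee (from the shank) and the hip (from the
#' thigh). Moments are reported extensor-positive (plantarflexion at the
#' ankle, extension at knee and hip). Each plate is assumed to carry one
#' foot; kinematics come from the lateral joint markers projected on the
#' sagittal plane, linear and angular accelerations from central
#' differences of the (filtered) trajectories. On flight frames the external
#' force is zero, so the net moments reduce to the (near-zero) inertial
#' residue of the ballistic segments.
#'
#' @param trial Preprocessed [jump_trial()] (GRF on the marker clock).
#' @param phases Optional [segment_phases()] result; only used to annotate
#'   stance/flight.
#' @param segments Segment parameters; defaults to
#'   `segment_params(trial$anthro)`.
#' @param side Leg side; the plate with the matching lateral sign is used,
#'   falling back to plate order (1 = left, 2 = right).
#' @return Tibble of class `joint_moments`: `time_s`, `frame`,
#'   `ankle_nm`, `knee_nm`, `hip_nm`, `in_flight`.
#' @export
inverse_dynamics <- function(trial, phases = NULL, segments = NULL,
                             side = "R") {
  stopifnot(inherits(trial, "jump_trial"))
  seg <- segments %||% segment_params(trial$anthro)
  mk <- trial$markers
  rate <- series_rate(mk)
  dt <- 1 / rate
  n <- nrow(mk)

  grf <- trial$grf
  plates <- sort(unique(grf$plate))
  plate_id <- if (side == "R") plates[length(plates)] else plates[1]
  gp <- grf[grf$plate == plate_id, ]
  if (nrow(gp) != n) abort("GRF is not on the marker clock")
  fy_ext <- if ("fy" %in% names(gp)) gp$fy else rep(0, n)
  fz_ext <- gp$fz
  cop_y <- if ("cop_y" %in% names(gp)) gp$cop_y / 1000 else rep(0, n)

  in_flight <- if (!is.null(phases)) {
    seq_len(n) >= phases$events[["takeoff"]] &
      seq_len(n) < phases$events[["touchdown"]]
  } else {
    fz_ext < 1e-9 & abs(fy_ext) < 1e-9
  }
  fz_ext[in_flight] <- 0
  fy_ext[in_flight] <- 0

  yz <- function(lbl) marker_xyz(mk, lbl)[, 2:3, drop = FALSE] / 1000  # m
  ankle <- yz(paste0(side, "ANK")); knee <- yz(paste0(side, "KNE"))
  hip <- yz(paste0(side, "GT")); toe <- yz(paste0(side, "TOE"))
  heel <- if (paste0(side, "HEE_Z") %in% names(mk)) {
    yz(paste0(side, "HEE"))
  } else {
    sweep(toe, 2, c(0.9 * trial$anthro$foot_cm / 100, 0), "-")
  }

  srow <- function(s) seg[seg$segment == s, ]
  prox <- list(foot = ankle, shank = knee, thigh = hip)
  dist <- list(foot = 0.5 * (heel + toe), shank = ankle, thigh = knee)
  # foot treated heel-to-toe; its "proximal" joint is the ankle

  acc2 <- function(x) apply(x, 2, function(cl) {
    d <- second_diff(cl, dt); d
  })
  # per-segment kinematics
  half_mass <- function(s) srow(s)$mass_kg  # per-side masses already
  res <- list()
  # distal load on the foot: plate force at the COP (z = 0)
  f_dist <- cbind(fy_ext, fz_ext)
  p_dist <- cbind(cop_y, 0)
  m_dist <- rep(0, n)
  for (s in c("foot", "shank", "thigh")) {
    pars <- srow(s)
    m_s <- pars$mass_kg
    com <- if (s == "foot") {
      heel + pars$com_fraction * (toe - heel)
    } else {
      prox[[s]] + pars$com_fraction * (dist[[s]] - prox[[s]])
    }
    theta <- if (s == "foot") {
      atan2(toe[, 2] - heel[, 2], toe[, 1] - heel[, 1])
    } else {
      atan2(prox[[s]][, 2] - dist[[s]][, 2], prox[[s]][, 1] - dist[[s]][, 1])
    }
    theta <- unwrap_angle(theta)
    alpha <- second_diff(theta, dt)
    a_com <- acc2(com)
    i_s <- m_s * (pars$gyration_fraction * pars$length_m)^2
    p_prox <- if (s == "foot") ankle else prox[[s]]
    # proximal joint force on this segment
    f_prox <- cbind(m_s * a_com[, 1] - f_dist[, 1],
                    m_s * a_com[, 2] + m_s * G_MS2 - f_dist[, 2])
    m_prox <- i_s * alpha -
      m_dist -
      cross2(p_dist[, 1] - com[, 1], p_dist[, 2] - com[, 2],
             f_dist[, 1], f_dist[, 2]) -
      cross2(p_prox[, 1] - com[, 1], p_prox[, 2] - com[, 2],
             f_prox[, 1], f_prox[, 2])
    res[[s]] <- m_prox
    # reaction on the next segment up
    f_dist <- -f_prox
    m_dist <- -m_prox
    p_dist <- p_prox
  }
  # extensor-positive sign convention: with +Y anterior and +Z up, a
  # counterclockwise internal moment is dorsiflexing at the ankle and
  # extending at the knee; flip ankle and hip so plantarflexion and hip
  # extension read positive
  out <- tibble::tibble(
    time_s = mk$time_s, frame = seq_len(n),
    ankle_nm = -res$foot, knee_nm = res$shank, hip_nm = -res$thigh,
    in_flight = in_flight)
  class(out) <- c("joint_moments", class(out))
  out
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Reduced planar muscle model
#'
#' Eight lower-limb actuators spanning ankle, knee and hip with constant
#' sagittal moment arms (m, extensor-positive: plantarflexion, knee
#' extension, hip extension) and tensile strengths proportional to body
#' weight. The full 31-muscle naming used in cohort reports maps onto these
#' groups via [muscle_group_labels()].
#'
#' @param mass_kg Body mass; strengths scale linearly with weight.
#' @return Tibble: `muscle`, `arm_ankle_m`, `arm_knee_m`, `arm_hip_m`,
#'   `strength_n`.
#' @export
default_muscle_model <- function(mass_kg = 18.4) {
  w <- mass_kg * G_MS2
  tibble::tribble(
    ~muscle, ~arm_ankle_m, ~arm_knee_m, ~arm_hip_m, ~strength_factor,
    "SOL",   0.035,  0.000,  0.000, 3.0,
    "TA",   -0.033,  0.000,  0.000, 1.0,
    "GAS",   0.040, -0.020,  0.000, 2.0,
    "VAS",   0.000,  0.042,  0.000, 4.0,
    "RF",    0.000,  0.048, -0.035, 2.0,
    "HAM",   0.000, -0.025,  0.055, 2.5,
    "GMAX",  0.000,  0.000,  0.060, 3.5,
    "ILPS",  0.000,  0.000, -0.040, 1.5) |>
    dplyr::mutate(strength_n = .data$strength_factor * w) |>
    dplyr::select(-"strength_factor")
}

#' Map of cohort muscle abbreviations onto the reduced model
#'
#' The 31 lower-limb muscle names used in cohort reporting (SM, SL, GL, GM,
#' ..., QF), each assigned to the reduced actuator group that carries its
#' mechanical role in the sagittal plane.
#'
#' @return Tibble with `abbrev`, `name`, `group`.
#' @export
muscle_group_labels <- function() {
  tibble::tribble(
    ~abbrev, ~name, ~group,
    "SM", "Soleus Medialis", "SOL",
    "SL", "Soleus Lateralis", "SOL",
    "GL", "Gastrocnemius Lateralis", "GAS",
    "GM", "Gastrocnemius Medialis", "GAS",
    "PB", "Peroneus Brevis", "SOL",
    "PL", "Peroneus Longus", "SOL",
    "VLI", "Vastus Lateralis Inferior", "VAS",
    "VLS", "Vastus Lateralis Superior", "VAS",
    "VMI", "Vastus Medialis Inferior", "VAS",
    "VMM", "Vastus Medialis Mid", "VAS",
    "VMS", "Vastus Medialis Superior", "VAS",
    "VI", "Vastus Intermedius", "VAS",
    "RF", "Rectus Femoris", "RF",
    "Sd", "Semitendinosus", "HAM",
    "Sb", "Semimembranosus", "HAM",
    "BFCL", "Biceps Femoris Caput Longum", "HAM",
    "GMiA", "Gluteus Minimus Anterior", "GMAX",
    "GMiM", "Gluteus Minimus Mid", "GMAX",
    "GMiP", "Gluteus Minimus Posterior", "GMAX",
    "GMeA", "Gluteus Medius Anterior", "GMAX",
    "GMeP", "Gluteus Medius Posterior", "GMAX",
    "GMaS", "Gluteus Maximus Superior", "GMAX",
    "GMaI", "Gluteus Maximus Inferior", "GMAX",
    "Pir", "Piriformis", "GMAX",
    "AMD", "Adductor Magnus Distal", "HAM",
    "AMM", "Adductor Magnus Mid", "HAM",
    "GI", "Gemellus Inferior", "GMAX",
    "GS", "Gemellus Superior", "GMAX",
    "OI", "Obturator Internus", "GMAX",
    "Pop", "Popliteus", "HAM",
    "QF", "Quadratus Femoris", "GMAX")
}

new_recruitment_solution <- function(f, strengths, objective, status,
                                     C, d) {
  resid <- if (status == "optimal") max(abs(C %*% f - d)) else NA_real_
  structure(list(f = as.numeric(f),
                 activations = as.numeric(f) / strengths,
                 objective = objective, status = status,
                 residual = resid),
            class = "recruitment_solution")
}

#' @export
print.recruitment_solution <- function(x, ...) {
  cat(sprintf("<recruitment_solution> status %s, objective %.6g\n",
              x$status, x$objective))
  if (x$status == "optimal") {
    cat("  f:", paste(sprintf("%.3f", x$f), collapse = " "), "\n")
  }
  invisible(x)
}

#' Solve the redundant muscle-recruitment problem
#'
#' Distributes a required generalized load `d` (net joint moments, N m)
#' over `n` muscles subject to the moment-balance equality `C f = d` and
#' tensile non-negativity `f >= 0`, minimizing a recruitment criterion on
#' the activations `a_i = f_i / N_i`:
#'
#' * `criterion = "polynomial"`: minimize `sum(a_i^p)` with `p >= 1`. `p = 2`
#'   is solved as a quadratic program; other `p` by a log-barrier interior
#'   method on the null space of `C` (unique solution for `p > 1`).
#' * `criterion = "minmax"`: minimize `max(a_i)` via the linear-programming
#'   reformulation (minimize `t` subject to `C f = d`, `0 <= f_i <= N_i t`),
#'   the "lowest physiological fatigue" strategy; ties among LP optima are
#'   broken by the minimum-norm force vector. As `p` grows, the polynomial
#'   solution approaches this one.
#'
#' @param C Moment-arm matrix, one row per balanced joint, one column per
#'   muscle (N m per N).
#' @param d Required joint load vector (N m).
#' @param strengths Per-muscle current tensile strength `N_i` (N), > 0.
#' @param criterion `"polynomial"` or `"minmax"`.
#' @param p Polynomial power, >= 1.
#' @param tol Equality/KKT tolerance.
#' @return A `recruitment_solution`: forces `f` (N), `activations`,
#'   `objective` (criterion value G), `status`, `residual`.
#' @examples
#' solve_recruitment(matrix(c(1, 1), 1), 10, c(50, 50))           # f = (5, 5)
#' solve_recruitment(matrix(c(1, 1), 1), 10, c(50, 50), "minmax") # G = 0.1
#' @export
solve_recruitment <- function(C, d, strengths,
                              criterion = c("polynomial", "minmax"),
                              p = 2, tol = 1e-8) {
  criterion <- match.arg(criterion)
  C <- as.matrix(C)
  d <- as.numeric(d)
  nm <- ncol(C)
  stopifnot(length(strengths) == nm, all(strengths > 0),
            nrow(C) == length(d))
  if (criterion == "polynomial" && p < 1) {
    abort("polynomial power p must be >= 1")
  }
  if (criterion == "minmax") {
    return(solve_minmax(C, d, strengths, tol))
  }
  if (p == 2) return(solve_poly2(C, d, strengths, tol))
  if (p == 1) return(solve_poly1(C, d, strengths, tol))
  solve_poly_barrier(C, d, strengths, p, tol)
}

solve_minmax <- function(C, d, strengths, tol = 1e-8) {
  nm <- ncol(C); nj <- nrow(C)
  # variables x = (f, t)
  cc <- c(rep(0, nm), 1)
  A <- cbind(diag(nm), -strengths)        # f_i - N_i t <= 0
  b <- rep(0, nm)
  Aeq <- cbind(C, rep(0, nj))
  sol <- tryCatch(
    pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = d, maxiter = 200),
    error = function(e) NULL)
  t_star <- if (!is.null(sol) && !is.null(sol$x) && sol$errno == 1) {
    sol$x[nm + 1]
  } else {
    # the simplex occasionally stalls; fall back to bisection on t with a
    # quadratic-program feasibility check of {Cf = d, 0 <= f <= N t}
    feasible_t <- function(t) {
      qp <- tryCatch(
        pracma::quadprog(diag(nm), rep(0, nm), Aeq = C, beq = d,
                         lb = rep(0, nm), ub = strengths * t),
        error = function(e) NULL)
      !is.null(qp) && !is.null(qp$xmin) &&
        max(abs(C %*% qp$xmin - d)) < 1e-6 * (1 + max(abs(d))) &&
        all(qp$xmin > -1e-8) && all(qp$xmin - strengths * t < 1e-6)
    }
    hi <- 1
    while (!feasible_t(hi) && hi < 1e6) hi <- hi * 2
    if (hi >= 1e6) {
      return(new_recruitment_solution(rep(NA_real_, nm), strengths,
                                      NA_real_, "infeasible", C, d))
    }
    lo <- 0
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (feasible_t(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  # minimum-norm tie-break among optimal vertices
  f <- tryCatch({
    qp <- pracma::quadprog(diag(nm), rep(0, nm), Aeq = C, beq = d,
                           lb = rep(0, nm),
                           ub = strengths * t_star * (1 + 1e-9) + 1e-12)
    qp$xmin
  }, error = function(e) sol$x[1:nm])
  new_recruitment_solution(f, strengths, t_star, "optimal", C, d)
}

solve_poly2 <- function(C, d, strengths, tol = 1e-8) {
  nm <- ncol(C)
  # no redundancy: the equality system pins f down
  ns <- pracma::nullspace(C)
  if (is.null(ns) || ncol(ns) == 0) {
    f <- tryCatch(qr.solve(C, d), error = function(e) NULL)
    if (is.null(f) || any(f < -1e-9) ||
        max(abs(C %*% f - d)) > 1e-6 * (1 + max(abs(d)))) {
      return(new_recruitment_solution(rep(NA_real_, nm), strengths, NA_real_,
                                      "infeasible", C, d))
    }
    f <- pmax(f, 0)
    return(new_recruitment_solution(f, strengths, sum((f / strengths)^2),
                                    "optimal", C, d))
  }
  sol <- tryCatch(
    pracma::quadprog(diag(2 / strengths^2), rep(0, nm), Aeq = C, beq = d,
                     lb = rep(0, nm)),
    error = function(e) NULL)
  if (is.null(sol) || is.null(sol$xmin) ||
      max(abs(C %*% sol$xmin - d)) > 1e-6 * (1 + max(abs(d)))) {
    return(new_recruitment_solution(rep(NA_real_, nm), strengths, NA_real_,
                                    "infeasible", C, d))
  }
  f <- pmax(sol$xmin, 0)
  new_recruitment_solution(f, strengths, sum((f / strengths)^2),
                           "optimal", C, d)
}

solve_poly1 <- function(C, d, strengths, tol = 1e-8) {
  nm <- ncol(C)
  sol <- tryCatch(
    pracma::linprog(1 / strengths, Aeq = C, beq = d, maxiter = 200),
    error = function(e) NULL)
  if (is.null(sol) || is.null(sol$x) || sol$errno != 1) {
    return(new_recruitment_solution(rep(NA_real_, nm), strengths, NA_real_,
                                    "infeasible", C, d))
  }
  f <- pmax(sol$x, 0)
  new_recruitment_solution(f, strengths, sum(f / strengths), "optimal", C, d)
}

# strictly interior feasible point: maximize the smallest force margin
# (Chebyshev-style LP); falls back to the p = 2 solution if degenerate
interior_feasible <- function(C, d, strengths) {
  nm <- ncol(C); nj <- nrow(C)
  sol <- tryCatch(
    pracma::linprog(c(rep(0, nm), -1),
                    A = cbind(-diag(nm), rep(1, nm)), b = rep(0, nm),
                    Aeq = cbind(C, 0), beq = d, maxiter = 200),
    error = function(e) NULL)
  if (!is.null(sol) && !is.null(sol$x) && sol$errno == 1 &&
      sol$x[nm + 1] > 1e-9) {
    return(sol$x[seq_len(nm)])
  }
  NULL
}

# log-barrier interior-point minimization of sum((f_i/N_i)^p) on the null
# space of C, warm-started along a homotopy in p (large powers are too
# ill-conditioned to attack directly); mu -> 0 recovers the constrained
# optimum, which is unique for p > 1
solve_poly_barrier <- function(C, d, strengths, p, tol = 1e-8) {
  nm <- ncol(C)
  ns <- pracma::nullspace(C)
  if (is.null(ns) || ncol(ns) == 0) {
    f <- tryCatch(qr.solve(C, d), error = function(e) NULL)
    if (is.null(f) || any(f < -1e-9)) {
      return(new_recruitment_solution(rep(NA_real_, nm), strengths,
                                      NA_real_, "infeasible", C, d))
    }
    f <- pmax(f, 0)
    return(new_recruitment_solution(f, strengths, sum((f / strengths)^p),
                                    "optimal", C, d))
  }
  f0 <- interior_feasible(C, d, strengths)
  if (is.null(f0)) {
    start <- solve_poly2(C, d, strengths)
    if (start$status != "optimal") return(start)
    f0 <- pmax(start$f, 1e-8 * max(1, max(abs(start$f))))
    corr <- tryCatch(qr.solve(C, d - C %*% f0), error = function(e) NULL)
    if (!is.null(corr)) f0 <- pmax(f0 + corr, 1e-10)
  }
  v <- rep(0, ncol(ns))
  fscale <- max(strengths)
  objgrad <- function(v, mu, pw) {
    f <- as.numeric(f0 + ns %*% v)
    if (any(f <= 0)) return(list(value = 1e12, grad = NULL))
    a <- f / strengths
    la <- log(a)
    ls <- max(pw * la) + log(sum(exp(pw * la - max(pw * la))))
    g <- exp(ls / pw)
    grad_f <- exp((1 / pw - 1) * ls + (pw - 1) * la) / strengths -
      mu / f
    list(value = g - mu * sum(log(f / fscale)),
         grad = as.numeric(crossprod(ns, grad_f)))
  }
  p_seq <- unique(c(pmin(2^(1:7), p), p))
  p_seq <- p_seq[p_seq > 1]
  for (pw in p_seq) {
    for (mu in 10^c(-3, -5, -7, -9, -11)) {
      opt <- stats::optim(
        v, fn = function(vv) objgrad(vv, mu, pw)$value,
        gr = function(vv) {
          g <- objgrad(vv, mu, pw)$grad
          if (is.null(g)) rep(0, length(vv)) else g
        },
        method = "BFGS", control = list(maxit = 400, reltol = 1e-15))
      v <- opt$par
    }
  }
  f <- pmax(as.numeric(f0 + ns %*% v), 0)
  new_recruitment_solution(f, strengths, sum((f / strengths)^p),
                           "optimal", C, d)
}

#' Body-weight-normalized muscle forces of a trial
#'
#' Runs the full dynamic chain: inverse dynamics for the net ankle, knee and
#' hip moments, then per-frame muscle recruitment over the stance phases
#' with the chosen criterion, collecting each muscle's peak force over the
#' trial divided by body weight (N/BW). Frames whose recruitment problem is
#' infeasible are skipped and counted.
#'
#' @param trial Preprocessed [jump_trial()].
#' @param phases [segment_phases()] result.
#' @param model Muscle model tibble (see [default_muscle_model()]).
#' @param criterion,p Passed to [solve_recruitment()].
#' @param side Leg side.
#' @param phases_use Phase names over which the peak is taken; `NULL`
#'   (default) uses every ground-contact phase of the jump.
#' @param min_force_n Frames whose plate force is below this (N) are
#'   excluded: the centre of pressure is undefined as the force vanishes.
#' @return Tibble of class `muscle_forces`: `muscle`, `peak_force_n`,
#'   `peak_force_bw`, `peak_activation`; attributes `n_infeasible`,
#'   `n_frames`.
#' @export
muscle_forces <- function(trial, phases, model = NULL,
                          criterion = "polynomial", p = 2, side = "R",
                          phases_use = NULL, min_force_n = 20) {
  model <- model %||% default_muscle_model(trial$anthro$mass_kg)
  mom <- inverse_dynamics(trial, phases, side = side)
  stance <- !mom$in_flight &
    mom$frame >= phases$events[["upright_start"]] &
    mom$frame < phases$events[["upright_end"]]
  # near the flight boundaries the plate force vanishes and the centre of
  # pressure is numerically undefined; such frames are conventionally
  # excluded from inverse-dynamics-driven recruitment
  plates <- sort(unique(trial$grf$plate))
  plate_id <- if (side == "R") plates[length(plates)] else plates[1]
  fz_plate <- trial$grf$fz[trial$grf$plate == plate_id]
  stance <- stance & fz_plate >= min_force_n
  if (!is.null(phases_use)) {
    keep <- rep(FALSE, nrow(mom))
    for (ph in phases_use) {
      r <- phases$phases[phases$phases$phase == ph, ]
      keep[seq(r$start, r$end - 1)] <- TRUE
    }
    stance <- stance & keep
  }
  C <- t(as.matrix(model[, c("arm_ankle_m", "arm_knee_m", "arm_hip_m")]))
  strengths <- model$strength_n
  peak <- rep(0, nrow(model))
  n_inf <- 0L
  for (i in which(stance)) {
    d <- c(mom$ankle_nm[i], mom$knee_nm[i], mom$hip_nm[i])
    sol <- solve_recruitment(C, d, strengths, criterion = criterion, p = p)
    if (sol$status != "optimal") { n_inf <- n_inf + 1L; next }
    peak <- pmax(peak, sol$f)
  }
  if (n_inf > 0) {
    warn(sprintf("%d stance frames had infeasible recruitment and were skipped",
                 n_inf))
  }
  bw <- trial$anthro$mass_kg * G_MS2
  out <- tibble::tibble(muscle = model$muscle, peak_force_n = peak,
                        peak_force_bw = peak / bw,
                        peak_activation = peak / strengths)
  attr(out, "n_infeasible") <- n_inf
  attr(out, "n_frames") <- sum(stance)
  class(out) <- c("muscle_forces", class(out))
  out
}
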
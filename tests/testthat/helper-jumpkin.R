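# shared fixtures, generated in code and cached for the session

.fixtures <- new.env(parent = emptyenv())

# the default-condition zero-noise trial, clean-processed (no filtering)
clean_trial <- function() {
  if (is.null(.fixtures$clean)) {
    tr <- generate_trial(jump_profile(), seed = 101)
    proc <- preprocess_trial(tr, marker_cutoff_hz = NULL,
                             grf_cutoff_hz = NULL, antialias = FALSE)
    proc$truth <- tr$truth
    .fixtures$clean <- list(raw = tr, proc = proc,
                            phases = segment_trial(proc))
  }
  .fixtures$clean
}

# the same trial through the standard 10/20 Hz processing
filtered_trial <- function() {
  if (is.null(.fixtures$filt)) {
    tr <- .fixtures$clean_raw %||% clean_trial()$raw
    proc <- preprocess_trial(tr)
    proc$truth <- tr$truth
    .fixtures$filt <- list(raw = tr, proc = proc,
                           phases = segment_trial(proc))
  }
  .fixtures$filt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# feasible profiles spanning the ballistic flight-time range; squat depth
# and push duration scale with the required takeoff velocity
ballistic_profile <- function(t_flight) {
  cfg <- list(`0.2` = c(D = 80, Tp = 0.21, B = 70, ext = 0.3),
              `0.3` = c(D = 150, Tp = 0.25, B = 110, ext = 0.6),
              `0.4` = c(D = 230, Tp = 0.33, B = 180, ext = 0.6),
              `0.5` = c(D = 330, Tp = 0.38, B = 270, ext = 0.6))
  v <- cfg[[as.character(t_flight)]]
  E <- v[["ext"]] * 0.5 * 165.8
  jump_profile(t_flight = t_flight, squat_depth_mm = v[["D"]],
               t_pushing = v[["Tp"]], buffer_depth_mm = v[["B"]],
               takeoff_extension = v[["ext"]],
               t_landing = (v[["B"]] + E) / (0.42 * 1000 * 9.81 * t_flight / 2))
}

# Exact brute-force oracle for the quadratic criterion: enumerate every
# subset of muscles pinned at zero; on the complement the equality-
# constrained minimizer of sum((f/N)^2) has the closed form
# f = W C' (C W C')^- d with W = diag(N^2). The optimum is the feasible
# candidate with the smallest objective.
p2_enumeration_oracle <- function(C, d, strengths) {
  nm <- ncol(C)
  best <- NULL
  for (mask in 0:(2^nm - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(nm) - 1)) == 0)
    if (length(free) == 0) next
    Cf <- C[, free, drop = FALSE]
    W <- diag(strengths[free]^2, length(free))
    M <- Cf %*% W %*% t(Cf)
    f_free <- tryCatch(W %*% t(Cf) %*% solve(M, d), error = function(e) NULL)
    if (is.null(f_free)) next
    f <- rep(0, nm)
    f[free] <- f_free
    if (any(f < -1e-9)) next
    if (max(abs(C %*% f - d)) > 1e-6 * (1 + max(abs(d)))) next
    val <- sum((f / strengths)^2)
    if (is.null(best) || val < best$value - 1e-15) {
      best <- list(f = pmax(f, 0), value = val)
    }
  }
  best
}

# Exact min/max oracle by LP vertex enumeration on x = (f, t):
# equalities Cf = d plus (nm + 1 - nj) active bounds chosen among
# {f_i = 0}, {f_i = N_i t}, {t = 0}; the optimum is the feasible vertex
# with the smallest t.
minmax_vertex_oracle <- function(C, d, strengths) {
  nm <- ncol(C); nj <- nrow(C)
  nv <- nm + 1
  # inequality rows as a x <= 0: f_i >= 0 -> -e_i; f_i - N_i t <= 0; t >= 0
  ineq <- rbind(cbind(-diag(nm), 0),
                cbind(diag(nm), -strengths),
                c(rep(0, nm), -1))
  eq <- cbind(C, 0)
  k <- nv - nj
  if (k < 0) return(NULL)
  best <- NULL
  for (combo in utils::combn(nrow(ineq), k, simplify = FALSE)) {
    A <- rbind(eq, ineq[combo, , drop = FALSE])
    b <- c(d, rep(0, k))
    x <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(x)) next
    f <- x[seq_len(nm)]; t <- x[nv]
    if (any(f < -1e-8) || t < -1e-10) next
    if (any(f - strengths * t > 1e-6)) next
    if (is.null(best) || t < best$value) best <- list(f = f, value = t)
  }
  best
}

# random feasible recruitment problem with <= 4 muscles and <= 2 joints;
# feasibility is guaranteed by building d from a positive force vector
random_recruitment_problem <- function() {
  nj <- sample(1:2, 1)
  nm <- sample((nj + 1):4, 1)
  C <- matrix(stats::runif(nj * nm, -0.06, 0.06), nj, nm)
  # ensure every row has both signs available so antagonists exist
  for (r in seq_len(nj)) {
    if (all(C[r, ] >= 0)) C[r, sample(nm, 1)] <- -stats::runif(1, 0.01, 0.06)
    if (all(C[r, ] <= 0)) C[r, sample(nm, 1)] <- stats::runif(1, 0.01, 0.06)
  }
  f_true <- stats::runif(nm, 0, 400)
  list(C = C, d = as.numeric(C %*% f_true),
       strengths = stats::runif(nm, 200, 1200))
}

balanced_toy <- function(reps = 4, seed = 3, null_b = FALSE) {
  set.seed(seed)
  df <- expand.grid(stage = c("i", "p", "m"), age_group = c(3, 4, 5),
                    rep = seq_len(reps))
  df$y <- rnorm(nrow(df), sd = 0.5) + 2 * as.numeric(df$stage)
  if (!null_b) df$y <- df$y + 0.8 * as.numeric(factor(df$age_group))
  df
}

# textbook sums-of-squares decomposition for a balanced two-way design
hand_anova <- function(df) {
  gm <- mean(df$y)
  a <- factor(df$stage); b <- factor(df$age_group)
  ssa <- sum(tapply(df$y, a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(df$y, b, function(v) length(v) * (mean(v) - gm)^2))
  cells <- tapply(df$y, list(a, b), mean)
  ncell <- table(a, b)[1, 1]
  ssab <- ncell * sum((cells - outer(tapply(df$y, a, mean),
                                     tapply(df$y, b, mean), `+`) + gm)^2)
  sst <- sum((df$y - gm)^2)
  sse <- sst - ssa - ssb - ssab
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfe <- nrow(df) - nlevels(a) * nlevels(b)
  list(ss = c(ssa, ssb, ssab), df = c(dfa, dfb, dfa * dfb),
       sse = sse, dfe = dfe,
       f = c(ssa / dfa, ssb / dfb, ssab / (dfa * dfb)) / (sse / dfe))
}
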
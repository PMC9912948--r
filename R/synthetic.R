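# Synthetic motion-capture trials with known ground truth. The generator
# rolls the model dynamics out with the same backward-Euler discretization
# the reconstruction uses, so a generated trajectory satisfies the
# collocation constraints to Newton tolerance, and synthesizes marker (175
# Hz) and force-plate (1750 Hz) recordings from it, including measurement
# noise, segment-coherent soft-tissue artifact and a shoe-sole offset of the
# contact geometry.

#' Find a static standing equilibrium
#'
#' Solves `f(x, 0, u) = 0` by damped Gauss-Newton over pelvis height, hip and
#' knee angles, actuator torques and muscle fiber lengths, with activations
#' held at a small baseline. Used to initialize rollouts and to synthesize
#' static N-pose trials.
#'
#' @param model an `msk_model` (toy-model DoF layout).
#' @param a0 baseline muscle activation.
#' @param q_init optional initial coordinate vector.
#' @return list with state `x`, controls `u` and the equilibrium residual.
#' @export
find_standing_state <- function(model, a0 = 0.05, q_init = NULL) {
  nd <- n_dof(model); nm <- n_mus(model); nt <- n_tor(model)
  if (is.null(q_init)) {
    q_init <- rep(0, nd)
    q_init[2] <- 1.0
  }
  # the template stacks the legs vertically over the fore-aft symmetric foot
  # contact, so the equilibrium needs essentially no joint torque and is the
  # effort-minimal standing pose; only the pelvis height is solved for
  free_q <- c(2L)
  pack <- function(p) {
    q <- q_init; q[free_q] <- p[seq_along(free_q)]
    m <- p[length(free_q) + seq_len(nt)]
    s <- if (nm) p[length(free_q) + nt + seq_len(nm)] else numeric(0)
    x <- state_vector(model, q, a = rep(a0, nm), s = s)
    u <- control_vector(model, n_e = rep(a0, nm), m = m)
    list(x = x, u = u)
  }
  resid <- function(p) {
    xu <- pack(p)
    cpp_dyn_residual(model_for_cpp(model), xu$x, rep(0, length(xu$x)), xu$u)
  }
  p <- c(q_init[free_q], rep(0, nt), rep(1, nm))
  f <- resid(p)
  # variable scales for the minimum-norm step: the torque/posture split is
  # underdetermined at symmetric poses, so keep the posture near the template
  # and let the actuators do the balancing
  psc <- c(rep(0.05, length(free_q)), rep(1, nt), rep(0.2, nm))
  for (it in 1:80) {
    if (max(abs(f)) < 1e-10) break
    J <- fd_jac(resid, p, 1e-7)
    Js <- sweep(J, 2, psc, "*")
    G <- crossprod(Js)
    lam <- 1e-10 * max(diag(G))
    step <- tryCatch(
      psc * solve(G + diag(lam, ncol(J)), crossprod(Js, -f))[, 1],
      error = function(e) NULL)
    if (is.null(step)) stop("standing equilibrium: singular Jacobian")
    alpha <- 1
    repeat {
      f1 <- resid(p + alpha * step)
      if (sum(f1^2) < sum(f^2) || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    p <- p + alpha * step
    f <- f1
  }
  if (max(abs(f)) > 1e-8)
    stop(sprintf("standing equilibrium did not converge (max residual %.2g)",
                 max(abs(f))))
  out <- pack(p)
  c(out, list(residual = f))
}

# Backward-Euler rollout: solves f(x[k+1], (x[k+1]-x[k])/h, u[k+1]) = 0 by
# Newton at every step, so the result satisfies the collocation dynamics.
rollout_implicit <- function(model, x0, u_fn, N, h) {
  nx <- n_states(model)
  X <- matrix(0, N, nx); U <- matrix(0, N, n_controls(model))
  X[1, ] <- x0
  for (k in seq_len(N - 1)) {
    u <- u_fn(k + 1, X[k, ], k * h)
    U[k + 1, ] <- u
    xprev <- X[k, ]
    g <- function(x1) cpp_dyn_residual(model_for_cpp(model), x1, (x1 - xprev) / h, u)
    x1 <- xprev
    f <- g(x1)
    for (it in 1:60) {
      if (max(abs(f)) < 1e-10) break
      J <- fd_jac(g, x1, 1e-7)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) stop(sprintf("rollout: singular Jacobian at node %d", k + 1))
      alpha <- 1
      repeat {
        f1 <- g(x1 + alpha * step)
        if (sum(f1^2) < sum(f^2) || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      x1 <- x1 + alpha * step
      f <- f1
    }
    if (max(abs(f)) > 1e-8)
      stop(sprintf("rollout did not converge at node %d (max residual %.2g)",
                   k + 1, max(abs(f))))
    X[k + 1, ] <- x1
  }
  U[1, ] <- U[2, ]
  list(X = X, U = U)
}

smoothstep <- function(t, t0, t1) {
  r <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  3 * r^2 - 2 * r^3
}

#' Generate a dynamically consistent reference motion
#'
#' Produces a ground-truth trajectory by rolling out the implicit dynamics
#' (backward Euler, Newton-solved at every node) under joint-space
#' proportional-derivative torques that follow a task-specific pose script,
#' plus scripted low-level muscle excitations. Both feet stay in ground
#' contact; the direction-change task pivots the pelvis about the vertical
#' axis through counter-rotation of the hips, producing a heading change of
#' at least 60 degrees. Because the rollout uses the same discretization as
#' the reconstruction, the trajectory satisfies the collocation dynamics
#' constraints to Newton tolerance.
#'
#' @param model an `msk_model` from [toy_model()], with the contact offset
#'   already set to its true value.
#' @param task `"straight"`, `"curved"` or `"direction_change"`.
#' @param seed RNG seed for the excitation phases.
#' @param N total node count, including lead-in context samples.
#' @param rate node rate in Hz.
#' @return an [msk_trajectory()] with attributes `task` and `seed`.
#' @export
generate_reference_motion <- function(model, task = c("straight", "curved",
                                                      "direction_change"),
                                      seed = 1, N = 70, rate = 175,
                                      turn_deg = NULL) {
  task <- match.arg(task)
  set.seed(seed)
  nd <- n_dof(model); nm <- n_mus(model)
  eq <- find_standing_state(model)
  q0 <- eq$x[seq_len(nd)]
  T <- (N - 1) / rate; h <- 1 / rate
  if (is.null(turn_deg))
    turn_deg <- switch(task, straight = 0, curved = 35, direction_change = 130)
  turn <- turn_deg * pi / 180
  bounce <- switch(task, straight = 0.05, curved = 0.04, direction_change = 0.04)
  crouch <- 0.12
  fb <- 1.5  # bounce frequency, Hz
  # left/right symmetric excitation phases: asymmetric drive would topple the
  # unactuated root over the trial duration
  ph2 <- stats::runif(2, 0, 2 * pi)
  phases <- if (nm == 4) ph2[c(1, 2, 1, 2)] else rep(ph2[1], max(nm, 1))
  q_target <- function(t) {
    qt <- q0
    # zero-velocity start and end of the crouch/bounce scripts: a velocity
    # step at the first node would put an impulsive acceleration transient
    # into the reference motion
    env <- smoothstep(t, 0, 0.12)
    b <- bounce * sin(2 * pi * fb * t) * env +
      crouch * sin(pi * pmin(t / T, 1))^2
    qt[c(8, 11)] <- q0[c(8, 11)] + 0.5 * b
    qt[c(9, 12)] <- q0[c(9, 12)] - b
    s <- smoothstep(t, 0.02, T - 0.02)
    qt[c(7, 10)] <- q0[c(7, 10)] - turn * s
    qt
  }
  # per-DoF gains sized to the apparent inertias (the one-step control delay
  # makes high derivative gain on the low-inertia hip-yaw DoF unstable)
  kp <- c(60, 250, 150)[c(1, 2, 3, 1, 2, 3)]
  kd <- c(6, 25, 15)[c(1, 2, 3, 1, 2, 3)]
  u_fn <- function(k, xprev, t) {
    q <- xprev[seq_len(nd)]; qd <- xprev[nd + seq_len(nd)]
    qt <- q_target(t)
    qtd <- (q_target(t + 1e-4) - q_target(t - 1e-4)) / 2e-4
    # balance: lean the legs against the pelvis obliquity/tilt deviation,
    # projected on each hip-pitch axis
    e5 <- q[5] - q0[5]; e6 <- q[6] - q0[6]
    qt[8] <- qt[8] + (sin(q[7]) * e5 + cos(q[7]) * e6)
    qt[11] <- qt[11] + (sin(q[10]) * e5 + cos(q[10]) * e6)
    m <- model$tor_gain * eq$u[nm + seq_len(n_tor(model))] +
      kp * (qt[7:12] - q[7:12]) + kd * (qtd[7:12] - qd[7:12])
    m <- pmin(pmax(m, -400), 400) / model$tor_gain
    ne <- if (nm) pmin(pmax(0.05 + 0.03 * sin(2 * pi * 1.5 * t + phases[seq_len(nm)]),
                            0.01), 1) else numeric(0)
    control_vector(model, n_e = ne, m = m)
  }
  ro <- rollout_implicit(model, eq$x, u_fn, N, h)
  traj <- msk_trajectory(model, ro$X, ro$U, T)
  if (task == "direction_change") {
    heading <- abs(traj$X[N, 4] - traj$X[1, 4]) * 180 / pi
    if (heading < 60)
      stop(sprintf("direction-change generation achieved only %.1f deg heading change",
                   heading))
  }
  attr(traj, "task") <- task
  attr(traj, "seed") <- seed
  attr(traj, "standing") <- eq
  traj
}

#' Corruption parameters for synthetic measurements
#'
#' @param marker_sd_mm iid Gaussian marker noise per axis (mm).
#' @param sta_amp_mm soft-tissue artifact amplitude on leg segments (mm).
#' @param sta_freq_hz soft-tissue artifact frequency (Hz).
#' @param grf_sd_n force-plate noise per axis (N).
#' @param sole_offset_mm true vertical offset of the contact points (shoe
#'   sole thickness) applied before generating the trial.
#' @return a named list.
#' @export
synthetic_corruption <- function(marker_sd_mm = 2, sta_amp_mm = 5,
                                 sta_freq_hz = 1.5, grf_sd_n = 3,
                                 sole_offset_mm = 12) {
  if (marker_sd_mm < 0 || sta_amp_mm < 0 || grf_sd_n < 0)
    stop("noise magnitudes must be non-negative")
  list(marker_sd_mm = marker_sd_mm, sta_amp_mm = sta_amp_mm,
       sta_freq_hz = sta_freq_hz, grf_sd_n = grf_sd_n,
       sole_offset_mm = sole_offset_mm)
}

#' Synthesize marker and force-plate measurements from a truth trajectory
#'
#' Clean markers are sampled from forward kinematics at the node rate (175
#' Hz); the corrupted copy adds iid Gaussian noise plus a segment-coherent
#' sinusoidal soft-tissue offset (random phase per segment and axis) on the
#' leg segments. Ground reaction forces, centers of pressure and vertical
#' free moments are sampled at 10x the node rate (1750 Hz) from the contact
#' model evaluated on linearly interpolated states -- consistent with the
#' piecewise-linear state assumption of the backward-Euler discretization --
#' with additive force noise.
#'
#' @param truth an [msk_trajectory()].
#' @param model the `msk_model` the truth was generated with (true contact
#'   offset applied).
#' @param corruption a [synthetic_corruption()] list.
#' @param seed RNG seed; the corruption is bit-reproducible given the seed.
#' @return list with `markers` (corrupted [marker_recording()]),
#'   `markers_clean`, and `plates` (a [forceplate_recording()]).
#' @export
synthesize_measurements <- function(truth, model, corruption = synthetic_corruption(),
                                    seed = 1) {
  set.seed(seed)
  nd <- n_dof(model)
  N <- truth$N
  pred <- cpp_predicted(model_for_cpp(model), truth$X, FALSE)
  clean <- 1000 * pred$markers  # mm
  nmark <- length(model$markers$dof)
  noise <- matrix(stats::rnorm(length(clean), 0, corruption$marker_sd_mm),
                  nrow = N)
  art <- matrix(0, N, 3 * nmark)
  segs <- unique(model$markers$dof[model$markers$dof > 6])
  for (sg in segs) {
    for (ax in 1:3) {
      phi <- stats::runif(1, 0, 2 * pi)
      offs <- corruption$sta_amp_mm *
        sin(2 * pi * corruption$sta_freq_hz * truth$times + phi)
      for (mi in which(model$markers$dof == sg))
        art[, 3 * (mi - 1) + ax] <- offs
    }
  }
  corrupted <- clean + noise + art
  mknames <- model$markers$name
  rate <- (N - 1) / truth$T
  rec_clean <- marker_recording(mknames, rate, clean)
  rec_corr <- marker_recording(mknames, rate, corrupted)
  # 1750 Hz states by linear interpolation between nodes
  sub <- 10
  Nf <- (N - 1) * sub + 1
  Xf <- matrix(0, Nf, ncol(truth$X))
  for (k in seq_len(N - 1)) {
    w <- seq(0, 1 - 1 / sub, length.out = sub)
    rows <- (k - 1) * sub + seq_len(sub)
    Xf[rows, ] <- outer(1 - w, truth$X[k, ]) + outer(w, truth$X[k + 1, ])
  }
  Xf[Nf, ] <- truth$X[N, ]
  ct <- cpp_contact_traj(model_for_cpp(model), Xf)
  plates <- list()
  for (foot in 0:1) {
    cols <- 3 * foot + 1:3
    force <- ct$grf[, cols, drop = FALSE] +
      matrix(stats::rnorm(3 * Nf, 0, corruption$grf_sd_n), Nf)
    plates[[foot + 1]] <- list(force = force,
                               cop = ct$cop[, cols, drop = FALSE],
                               moment = cbind(0, ct$free_moment[, foot + 1], 0))
  }
  list(markers = rec_corr, markers_clean = rec_clean,
       plates = forceplate_recording(rate * sub, plates))
}

#' Generate a complete synthetic trial
#'
#' End-to-end fixture: applies the true sole offset to the contact geometry,
#' finds the standing equilibrium, generates a reference motion, synthesizes
#' corrupted measurements and a clean static N-pose trial, and records the
#' manifest (seed, task, corruption parameters, motion-of-interest span).
#'
#' @param model base `msk_model` (offset as configured is overwritten by the
#'   true sole offset).
#' @param task motion task, see [generate_reference_motion()].
#' @param seed RNG seed for motion and corruption.
#' @param N_moi nodes in the motion of interest.
#' @param n_pre lead-in context samples before the motion of interest.
#' @param n_post trailing samples after the motion of interest (the inverse
#'   pipeline filters whole recordings, so the analyzed span must not touch
#'   the recording edge).
#' @param corruption a [synthetic_corruption()] list.
#' @return object of class `synthetic_trial`: `truth`, `model_true` (offset
#'   applied), `model` (offset zeroed, as handed to reconstruction),
#'   recordings, static trial, `moi` span and manifest.
#' @export
generate_synthetic_trial <- function(model = toy_model(), task = "direction_change",
                                     seed = 1, N_moi = 60, n_pre = 10,
                                     n_post = 10,
                                     corruption = synthetic_corruption()) {
  model_true <- model
  model_true$contacts$offset <- corruption$sole_offset_mm / 1000
  N <- N_moi + n_pre + n_post
  truth <- generate_reference_motion(model_true, task, seed = seed, N = N)
  meas <- synthesize_measurements(truth, model_true, corruption, seed = seed + 1000L)
  eq <- attr(truth, "standing")
  nd <- n_dof(model)
  static_mk <- 1000 * cpp_markers(model_for_cpp(model_true), eq$x[seq_len(nd)])
  static_grf <- cpp_contact(model_for_cpp(model_true), eq$x[seq_len(nd)],
                            rep(0, nd))$grf
  model_blind <- model
  model_blind$contacts$offset <- 0
  structure(list(
    truth = truth, model_true = model_true, model = model_blind,
    markers = meas$markers, markers_clean = meas$markers_clean,
    plates = meas$plates,
    static = list(markers_mm = as.vector(t(static_mk)), grf_n = static_grf,
                  x = eq$x, u = eq$u),
    moi = c(n_pre + 1L, n_pre + N_moi + 1L),
    manifest = list(task = task, seed = seed, N_moi = N_moi, n_pre = n_pre,
                    n_post = n_post, corruption = corruption)),
    class = "synthetic_trial")
}

#' Build a tracking dataset from a synthetic trial
#'
#' Marker mode tracks the corrupted marker recording (mm); coordinate mode
#' tracks pelvis translations (mm) and angles (deg) estimated by inverse
#' kinematics from the same corrupted markers. Both track the force-plate
#' recording decimated to the marker rate and scaled to BW%.
#'
#' @param trial a [generate_synthetic_trial()] result.
#' @param mode `"marker"` or `"coordinate"`.
#' @param ik an `msk_ik` fit (required for coordinate mode).
#' @return a [tracking_data()] spanning the full recording, with `moi` set.
#' @export
make_tracking_data <- function(trial, mode = c("marker", "coordinate"), ik = NULL) {
  mode <- match.arg(mode)
  model <- trial$model
  bw <- model$body_mass * 9.81
  grf_ds <- downsample_grf(trial$plates, trial$markers$rate)
  y_grf <- 100 / bw * cbind(grf_ds$plates[[1]]$force, grf_ds$plates[[2]]$force)
  n <- nrow(trial$markers$pos)
  y_grf <- y_grf[seq_len(n), , drop = FALSE]
  types <- list(grf = list(y = y_grf, unit = "BW%"))
  if (mode == "marker") {
    mask3 <- trial$markers$mask[, rep(seq_len(ncol(trial$markers$mask)), each = 3),
                                drop = FALSE]
    types$marker <- list(y = trial$markers$pos, mask = mask3, unit = "mm")
  } else {
    if (is.null(ik)) stop("coordinate mode needs an inverse-kinematics fit")
    nd <- n_dof(model)
    types$translation <- list(y = 1000 * ik$Q[, 1:3, drop = FALSE], unit = "mm")
    types$angle <- list(y = 180 / pi * ik$Q[, 4:nd, drop = FALSE], unit = "deg")
  }
  tracking_data(types, rate = trial$markers$rate, moi = trial$moi)
}

#' Build the single-node standing dataset from a synthetic trial
#'
#' @param trial a [generate_synthetic_trial()] result.
#' @param mode `"marker"` or `"coordinate"`.
#' @return a [tracking_data()] with one node.
#' @export
make_static_tracking_data <- function(trial, mode = c("marker", "coordinate")) {
  mode <- match.arg(mode)
  bw <- trial$model$body_mass * 9.81
  types <- list(grf = list(y = matrix(100 / bw * trial$static$grf_n, 1), unit = "BW%"))
  if (mode == "marker") {
    types$marker <- list(y = matrix(trial$static$markers_mm, 1), unit = "mm")
  } else {
    nd <- n_dof(trial$model)
    q <- trial$static$x[seq_len(nd)]
    types$translation <- list(y = matrix(1000 * q[1:3], 1), unit = "mm")
    types$angle <- list(y = matrix(180 / pi * q[4:nd], 1), unit = "deg")
  }
  tracking_data(types, rate = trial$markers$rate)
}
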
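# Model definition and elementary model evaluations (kinematics, implicit
# dynamics residual, contact, muscles, passive moments).
#
# Internal conventions: right-handed lab frame with vertical = +Y, ground at
# y = 0, SI units, angles in radians. Degrees and millimeters appear only at
# file interfaces and in tracking objectives.

#' Construct a musculoskeletal model definition
#'
#' Builds and validates the articulated model used by all solvers. The model
#' is a rooted kinematic tree of single-degree-of-freedom joints: the first
#' six DoFs are the global pelvis coordinates (three translations, then three
#' rotations with the vertical-axis rotation first so that heading can be
#' read off a single coordinate). Segments with inertia, markers, penetration
#' contact points, polynomial-path muscles and torque actuators attach to DoF
#' frames.
#'
#' @param dof list with `name`, `parent` (integer, 0 = world), `jtype`
#'   (0 translation, 1 rotation), `axis` (n x 3, unit vectors in the parent
#'   frame), `trans` (n x 3, joint origin offset in the parent frame, m).
#' @param body list with `name`, `dof` (frame index), `mass` (kg), `com`
#'   (n x 3, m, local), `inertia` (n x 9, row-major 3x3 about the CoM,
#'   kg m^2, local frame).
#' @param markers list with `name`, `dof`, `local` (n x 3, m).
#' @param contacts list with `dof`, `foot` (0 right, 1 left), `local`
#'   (n x 3, m) and scalar parameters `k` (N/m^expn), `expn`, `cdamp` (s/m),
#'   `mu`, `vs` (m/s), `eps` (m), `offset` (m, calibrated vertical offset of
#'   the ground contact geometry).
#' @param muscles list with `name`, `fmax` (N), `lmopt` (m), `ltslack` (m),
#'   `vmax` (optimal fiber lengths/s), `tact`, `tdeact` (s), `w`
#'   (volume weight, dimensionless), `kt` (tendon exponential stiffness,
#'   dimensionless), `rigid` (0/1 rigid-tendon debug switch)
#'   and `poly`, a list per muscle of `coef` and integer exponent matrix
#'   `expo` (terms x n_dof) defining the muscle-tendon length over the
#'   coordinates (radians in, meters out).
#' @param tor integer vector of DoF indices driven by torque actuators.
#' @param tor_gain torque per unit control (N m) for each actuator; the
#'   dimensionless controls keep the effort weighting comparable to the
#'   normalized neural excitations.
#' @param passive list with per-DoF `qlo`, `qhi` (rad; range-of-motion
#'   limits), `k` (N m), `b` (1/rad) and `d` (N m s/rad) of the exponential
#'   limit stiffening plus linear damping.
#' @param ranges n x 2 matrix of optimization bounds per coordinate.
#' @param gravity gravity vector (m/s^2).
#' @param body_mass,body_height subject scale (kg, m) used for unit scalings.
#' @param name model name.
#' @param allow_point_mass permit zero rotational inertia (test fixtures only).
#' @return an object of class `msk_model`.
#' @export
msk_model <- function(dof, body, markers, contacts, muscles, tor,
                      tor_gain = rep(1, length(tor)), passive,
                      ranges, gravity = c(0, -9.81, 0), body_mass, body_height,
                      name = "model", allow_point_mass = FALSE) {
  m <- list(name = name, dof = dof, body = body, markers = markers,
            contacts = contacts, muscles = muscles, tor = as.integer(tor),
            tor_gain = as.numeric(tor_gain),
            passive = passive, ranges = ranges, gravity = gravity,
            body_mass = body_mass, body_height = body_height)
  class(m) <- "msk_model"
  validate_model(m, allow_point_mass = allow_point_mass)
  m
}

#' Validate a model definition
#'
#' Checks all structural invariants and reports every violation found, not
#' just the first.
#'
#' @param model an `msk_model`.
#' @param allow_point_mass permit degenerate (zero) rotational inertia.
#' @return the model, invisibly.
#' @export
validate_model <- function(model, allow_point_mass = FALSE) {
  errs <- character()
  nd <- length(model$dof$parent)
  if (nd < 6) errs <- c(errs, "model needs at least the 6 global pelvis DoFs")
  p <- model$dof$parent
  if (any(p >= seq_len(nd)))
    errs <- c(errs, "DoF graph is not a rooted tree ordered parent-before-child")
  if (nd >= 6) {
    if (!all(model$dof$jtype[1:3] == 0) || !all(model$dof$jtype[4:6] == 1))
      errs <- c(errs, "global DoFs must be 3 translations followed by 3 rotations")
  }
  if (any(model$body$mass <= 0)) errs <- c(errs, "segment masses must be > 0")
  for (b in seq_along(model$body$mass)) {
    I <- matrix(model$body$inertia[b, ], 3, 3, byrow = TRUE)
    if (max(abs(I - t(I))) > 1e-12)
      errs <- c(errs, sprintf("inertia tensor of body %d is not symmetric", b))
    ev <- eigen(0.5 * (I + t(I)), only.values = TRUE)$values
    if (any(ev < 0) || (!allow_point_mass && any(ev <= 0)))
      errs <- c(errs, sprintf("inertia tensor of body %d is not positive definite", b))
  }
  if (any(model$markers$dof < 1 | model$markers$dof > nd))
    errs <- c(errs, "marker references a non-existing DoF frame")
  if (any(model$contacts$dof < 1 | model$contacts$dof > nd))
    errs <- c(errs, "contact point references a non-existing DoF frame")
  if (n_mus(model) > 0) {
    if (any(model$muscles$w <= 0)) errs <- c(errs, "muscle volume weights must be > 0")
    if (any(model$muscles$tact <= 0) || any(model$muscles$tdeact <= 0))
      errs <- c(errs, "muscle time constants must be > 0")
    if (any(model$muscles$fmax <= 0)) errs <- c(errs, "muscle fmax must be > 0")
  }
  if (any(model$tor < 1 | model$tor > nd))
    errs <- c(errs, "torque actuator references a non-existing DoF")
  if (length(model$tor_gain) != length(model$tor) || any(model$tor_gain <= 0))
    errs <- c(errs, "torque actuator gains must be positive, one per actuator")
  if (length(errs) > 0)
    stop("invalid model definition:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(model)
}

#' @rdname model_dims
#' @export
n_dof <- function(model) length(model$dof$parent)
#' @rdname model_dims
#' @export
n_mus <- function(model) length(model$muscles$fmax)
#' Model dimensions
#'
#' Number of coordinates, muscles, torque actuators, states
#' (`2 n_dof + 2 n_mus`), controls (`n_mus + n_tor`) and dynamics-residual
#' rows of a model.
#' @param model an `msk_model`.
#' @return an integer.
#' @rdname model_dims
#' @export
n_tor <- function(model) length(model$tor)
#' @rdname model_dims
#' @export
n_states <- function(model) 2L * n_dof(model) + 2L * n_mus(model)
#' @rdname model_dims
#' @export
n_controls <- function(model) n_mus(model) + n_tor(model)
#' @rdname model_dims
#' @export
n_residual <- function(model) 2L * n_dof(model) + 2L * n_mus(model)

# Pack/unpack helpers for the state and control vectors.
state_vector <- function(model, q, qdot = NULL, a = NULL, s = NULL) {
  nd <- n_dof(model); nm <- n_mus(model)
  if (is.null(qdot)) qdot <- rep(0, nd)
  if (is.null(a)) a <- rep(0, nm)
  if (is.null(s)) s <- rep(1, nm)
  stopifnot(length(q) == nd, length(qdot) == nd, length(a) == nm, length(s) == nm)
  c(q, qdot, a, s)
}

split_state <- function(model, x) {
  nd <- n_dof(model); nm <- n_mus(model)
  list(q = x[seq_len(nd)], qdot = x[nd + seq_len(nd)],
       a = if (nm) x[2 * nd + seq_len(nm)] else numeric(0),
       s = if (nm) x[2 * nd + nm + seq_len(nm)] else numeric(0))
}

control_vector <- function(model, n_e = NULL, m = NULL) {
  nm <- n_mus(model); nt <- n_tor(model)
  if (is.null(n_e)) n_e <- rep(0, nm)
  if (is.null(m)) m <- rep(0, nt)
  stopifnot(length(n_e) == nm, length(m) == nt)
  c(n_e, m)
}

# Internal: model list in the layout the compiled core expects.
model_for_cpp <- function(model) model

#' Forward kinematics
#'
#' World rigid transform of every DoF frame and world position of every
#' marker for a coordinate vector.
#'
#' @param model an `msk_model`.
#' @param q coordinate vector (m / rad), length `n_dof(model)`.
#' @return list with `origins` (n_dof x 3, m), `rotations` (3 x 3 x n_dof)
#'   and `markers` (n_markers x 3, m).
#' @export
forward_kinematics <- function(model, q) {
  if (length(q) != n_dof(model))
    stop(sprintf("q has length %d, model has %d DoFs", length(q), n_dof(model)))
  if (!all(is.finite(q))) stop("non-finite coordinates in q")
  fk <- cpp_fk(model_for_cpp(model), as.numeric(q))
  rownames(fk$markers) <- model$markers$name
  fk
}

#' Implicit dynamics residual
#'
#' Evaluates the implicit model dynamics f(x, xdot, u). The residual has four
#' blocks: kinematic identities (qdot - dq/dt), multibody equations of motion
#' (including gravity, ground contact, muscle moments, passive moments and
#' actuator torques), muscle activation dynamics, and muscle contraction
#' (Hill force balance) dynamics. A zero vector means the dynamics are
#' satisfied.
#'
#' @param model an `msk_model`.
#' @param x state vector (length `n_states(model)`).
#' @param xdot candidate continuous-time state derivative.
#' @param u control vector (length `n_controls(model)`).
#' @return named residual vector of length `n_residual(model)`.
#' @export
implicit_dynamics_residual <- function(model, x, xdot, u) {
  nd <- n_dof(model); nm <- n_mus(model)
  stopifnot(length(x) == n_states(model), length(xdot) == n_states(model),
            length(u) == n_controls(model))
  for (nmv in c("x", "xdot", "u")) {
    v <- get(nmv)
    if (!all(is.finite(v))) {
      blk <- dyn_block_of(model, which(!is.finite(v))[1], nmv)
      stop(sprintf("non-finite value in %s (block: %s)", nmv, blk))
    }
  }
  r <- cpp_dyn_residual(model_for_cpp(model), as.numeric(x), as.numeric(xdot),
                        as.numeric(u))
  names(r) <- dyn_residual_names(model)
  r
}

dyn_residual_names <- function(model) {
  nd <- n_dof(model); nm <- n_mus(model)
  c(paste0("kin_", model$dof$name),
    paste0("mb_", model$dof$name),
    if (nm) paste0("act_", model$muscles$name),
    if (nm) paste0("con_", model$muscles$name))
}

dyn_block_of <- function(model, idx, which_vec) {
  nd <- n_dof(model); nm <- n_mus(model)
  if (which_vec == "u") return(if (idx <= nm) "neural excitation" else "actuator torque")
  if (idx <= nd) "coordinates" else if (idx <= 2 * nd) "velocities"
  else if (idx <= 2 * nd + nm) "activation" else "contraction"
}

#' Ground contact forces
#'
#' Penetration-based contact law, evaluated at every contact point. The
#' vertical force is `k * sp(d)^expn * (1 + cdamp * penetration velocity)`
#' where `sp` is a softplus smoothing of the penetration depth `d`, and the
#' horizontal force is a velocity-smoothed Coulomb friction bounded by
#' `mu` times the vertical force. The law is continuously differentiable in
#' all states.
#'
#' @param model an `msk_model`.
#' @param q,qdot coordinates and velocities.
#' @return list with `points` (world positions, m), `forces` (N),
#'   `grf_right`, `grf_left` (net 3D ground reaction force per foot, N).
#' @export
ground_contact_forces <- function(model, q, qdot) {
  stopifnot(length(q) == n_dof(model), length(qdot) == n_dof(model))
  ct <- cpp_contact(model_for_cpp(model), as.numeric(q), as.numeric(qdot))
  list(points = ct$points, forces = ct$forces,
       grf_right = ct$grf[1:3], grf_left = ct$grf[4:6])
}

#' Muscle dynamics residuals
#'
#' Activation block: first-order dynamics with distinct activation and
#' deactivation time constants (smoothly switched); zero iff `adot` matches
#' the excitation-driven rate. Contraction block: implicit Hill-type force
#' balance between the series-elastic tendon and the contractile plus
#' parallel-elastic fiber forces; zero iff `sdot` is consistent.
#'
#' @param model an `msk_model` (with at least one muscle).
#' @param a,adot activations and their derivatives.
#' @param s,sdot normalized fiber lengths and their derivatives.
#' @param n_e neural excitations.
#' @param q coordinates (determines muscle-tendon lengths).
#' @return list with `activation` and `contraction` residual vectors and the
#'   `tendon_force` (N) applied to the skeleton.
#' @export
muscle_dynamics_residual <- function(model, a, adot, s, sdot, n_e, q) {
  nm <- n_mus(model)
  stopifnot(nm > 0, length(a) == nm, length(adot) == nm, length(s) == nm,
            length(sdot) == nm, length(n_e) == nm, length(q) == n_dof(model))
  cpp_muscle_residual(model_for_cpp(model), as.numeric(a), as.numeric(adot),
                      as.numeric(s), as.numeric(sdot), as.numeric(n_e),
                      as.numeric(q))
}

#' Muscle-tendon lengths and moment arms
#'
#' Polynomial muscle-tendon lengths over the coordinates; moment arms are the
#' negative partial derivatives of the length with respect to each angle.
#'
#' @param model an `msk_model`.
#' @param q coordinate vector.
#' @return list with `lmt` (m) and `moment_arm` (n_mus x n_dof, m).
#' @export
muscle_geometry <- function(model, q) {
  stopifnot(length(q) == n_dof(model))
  cpp_lmt_ma(model_for_cpp(model), as.numeric(q))
}

#' Passive joint moments
#'
#' Near-zero inside the configured range of motion, exponentially stiffening
#' beyond the limits, plus linear velocity damping.
#'
#' @param model an `msk_model`.
#' @param q,qdot coordinates and velocities.
#' @return per-DoF passive generalized force (N m, or N for translations).
#' @export
passive_joint_moment <- function(model, q, qdot) {
  stopifnot(length(q) == n_dof(model), length(qdot) == n_dof(model))
  cpp_passive_moment(model_for_cpp(model), as.numeric(q), as.numeric(qdot))
}

#' Write a model definition to a YAML config file
#'
#' @param model an `msk_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser <- unclass(model)
  ser$dof$axis <- as.vector(t(ser$dof$axis)); ser$dof$trans <- as.vector(t(ser$dof$trans))
  ser$body$com <- as.vector(t(ser$body$com)); ser$body$inertia <- as.vector(t(ser$body$inertia))
  ser$markers$local <- as.vector(t(ser$markers$local))
  ser$contacts$local <- as.vector(t(ser$contacts$local))
  ser$ranges <- as.vector(t(ser$ranges))
  ser$muscles$poly <- lapply(ser$muscles$poly, function(p)
    list(coef = p$coef, expo = as.vector(t(p$expo)), nterm = nrow(p$expo)))
  ser$units <- list(length = "m", angle = "rad", mass = "kg", force = "N")
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a model definition from a YAML config file
#'
#' The loader validates all structural invariants and reports every violation.
#'
#' @param path file written by [write_model()] (or hand-authored in the same
#'   layout).
#' @return an `msk_model`.
#' @export
read_model <- function(path) {
  ser <- yaml::read_yaml(path)
  nd <- length(ser$dof$parent)
  ser$dof$axis <- matrix(ser$dof$axis, ncol = 3, byrow = TRUE)
  ser$dof$trans <- matrix(ser$dof$trans, ncol = 3, byrow = TRUE)
  ser$dof$parent <- as.integer(ser$dof$parent)
  ser$dof$jtype <- as.integer(ser$dof$jtype)
  ser$body$com <- matrix(ser$body$com, ncol = 3, byrow = TRUE)
  ser$body$inertia <- matrix(ser$body$inertia, ncol = 9, byrow = TRUE)
  ser$body$dof <- as.integer(ser$body$dof)
  ser$markers$local <- matrix(ser$markers$local, ncol = 3, byrow = TRUE)
  ser$markers$dof <- as.integer(ser$markers$dof)
  ser$contacts$local <- matrix(ser$contacts$local, ncol = 3, byrow = TRUE)
  ser$contacts$dof <- as.integer(ser$contacts$dof)
  ser$contacts$foot <- as.integer(ser$contacts$foot)
  ser$ranges <- matrix(ser$ranges, ncol = 2, byrow = TRUE)
  ser$muscles$poly <- lapply(ser$muscles$poly, function(p)
    list(coef = as.numeric(p$coef),
         expo = matrix(as.integer(p$expo), nrow = p$nterm, ncol = nd, byrow = TRUE)))
  ser$muscles$rigid <- as.integer(ser$muscles$rigid)
  ser$units <- NULL
  msk_model(dof = ser$dof, body = ser$body, markers = ser$markers,
            contacts = ser$contacts, muscles = ser$muscles, tor = ser$tor,
            tor_gain = as.numeric(ser$tor_gain),
            passive = ser$passive, ranges = ser$ranges,
            gravity = as.numeric(ser$gravity), body_mass = ser$body_mass,
            body_height = ser$body_height, name = ser$name)
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("Musculoskeletal model '%s'\n", x$name))
  cat(sprintf("  %d DoFs (6 global), %d segments, %d markers\n",
              n_dof(x), length(x$body$mass), length(x$markers$dof)))
  cat(sprintf("  %d muscles, %d torque actuators, %d contact points\n",
              n_mus(x), n_tor(x), length(x$contacts$dof)))
  cat(sprintf("  body mass %.1f kg, height %.2f m, contact offset %.1f mm\n",
              x$body_mass, x$body_height, 1000 * x$contacts$offset))
  invisible(x)
}
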
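# Objective terms of the reconstruction problem and their containers.

#' Discretized trajectory
#'
#' States and controls at N collocation nodes spanning a duration T with step
#' h = T/(N-1).
#'
#' @param model an `msk_model`.
#' @param X N x n_states state matrix (coordinates in m/rad, velocities,
#'   activations, normalized fiber lengths).
#' @param U N x n_controls control matrix (excitations, actuator torques N m).
#' @param T duration in seconds.
#' @param t0 time of the first node (s).
#' @return object of class `msk_trajectory`.
#' @export
msk_trajectory <- function(model, X, U, T, t0 = 0) {
  X <- as.matrix(X); U <- matrix(as.matrix(U), nrow = nrow(X))
  N <- nrow(X)
  if (N < 2) stop("a trajectory needs at least 2 nodes")
  if (ncol(X) != n_states(model))
    stop(sprintf("X has %d columns, model has %d states", ncol(X), n_states(model)))
  if (ncol(U) != n_controls(model))
    stop(sprintf("U has %d columns, model has %d controls", ncol(U), n_controls(model)))
  if (T <= 0) stop("duration must be positive")
  structure(list(N = N, T = T, h = T / (N - 1), X = X, U = U,
                 times = t0 + seq(0, T, length.out = N)),
            class = "msk_trajectory")
}

#' Tracking dataset
#'
#' Reference signals by data type. Supported types: `translation` (pelvis
#' translations, mm), `angle` (orientation and joint angles, deg), `marker`
#' (stacked marker coordinates, mm), `grf` (right then left 3D ground
#' reaction force, BW%). Each type holds a reference matrix `y`
#' (N x N_signals), a logical validity `mask` of the same shape (FALSE =
#' occluded, excluded from costs) and its unit string.
#'
#' @param types named list of lists with `y`, optional `mask`, `unit`.
#' @param rate sampling rate (Hz).
#' @param moi motion-of-interest node span, half-open `[start, end)`,
#'   1-based indices into the rows of `y`.
#' @return object of class `tracking_data`.
#' @export
tracking_data <- function(types, rate, moi = NULL) {
  stopifnot(length(types) > 0)
  N <- nrow(types[[1]]$y)
  default_units <- c(translation = "mm", angle = "deg", marker = "mm", grf = "BW%")
  for (j in names(types)) {
    types[[j]]$y <- as.matrix(types[[j]]$y)
    if (nrow(types[[j]]$y) != N) stop("all data types must share the node count")
    if (is.null(types[[j]]$mask))
      types[[j]]$mask <- matrix(TRUE, nrow(types[[j]]$y), ncol(types[[j]]$y))
    if (!identical(dim(types[[j]]$mask), dim(types[[j]]$y)))
      stop(sprintf("mask shape of type '%s' does not match its data", j))
    if (is.null(types[[j]]$unit)) types[[j]]$unit <- default_units[[j]]
  }
  if (is.null(moi)) moi <- c(1L, N + 1L)
  structure(list(types = types, N = N, rate = rate,
                 times = (seq_len(N) - 1) / rate, moi = as.integer(moi)),
            class = "tracking_data")
}

#' Objective weights
#'
#' Default weights of the multi-objective function per tracking mode and
#' problem phase. Tracking weights are per squared signal unit
#' (mm^-2 for translations and markers, deg^-2 for angles, (BW%)^-2 for
#' ground reaction forces); effort and regularization weights are
#' dimensionless. Standing problems use a larger GRF weight and no
#' regularization.
#'
#' @param mode `"marker"` or `"coordinate"` tracking.
#' @param phase `"running"` (motion reconstruction) or `"standing"`.
#' @return object of class `objective_weights` with elements `W_tra`
#'   (named vector), `W_mus`, `W_tor`, `W_reg` and `units`.
#' @export
objective_weights <- function(mode = c("marker", "coordinate"),
                              phase = c("running", "standing")) {
  mode <- match.arg(mode); phase <- match.arg(phase)
  W_grf <- if (phase == "standing") 1e-2 else 1e-3
  W_tra <- if (mode == "marker") c(marker = 1e-2, grf = W_grf)
           else c(translation = 1e-3, angle = 1e-1, grf = W_grf)
  structure(list(W_tra = W_tra, W_mus = 1, W_tor = 1e-1,
                 W_reg = if (phase == "standing") 0 else 1e-3,
                 units = c(translation = "mm", angle = "deg",
                           marker = "mm", grf = "BW%")),
            class = "objective_weights")
}

#' Tracking cost
#'
#' Weighted mean squared difference between reference and predicted signals,
#' summed over the active data types:
#' `J_tra = sum_j W_j/(N N_j) sum_k sum_i (y - yhat)^2`.
#' Masked (occluded) entries contribute zero without changing `N_j`.
#'
#' @param data a [tracking_data()] object.
#' @param predicted named list of predicted signal matrices, same shapes and
#'   units as the reference types.
#' @param weights an [objective_weights()] object.
#' @return scalar cost.
#' @export
tracking_cost <- function(data, predicted, weights) {
  J <- 0
  for (j in names(data$types)) {
    ty <- data$types[[j]]
    if (!is.null(weights$units[j]) && !is.na(weights$units[j]) &&
        ty$unit != weights$units[[j]])
      stop(sprintf("unit mismatch for type '%s': data in %s, weight per %s^-2",
                   j, ty$unit, weights$units[[j]]))
    W <- weights$W_tra[[j]]
    yhat <- as.matrix(predicted[[j]])
    if (!identical(dim(yhat), dim(ty$y)))
      stop(sprintf("predicted '%s' has wrong shape", j))
    d <- (ty$y - yhat)
    d[!ty$mask] <- 0
    J <- J + W / (nrow(ty$y) * ncol(ty$y)) * sum(d^2)
  }
  J
}

#' Muscular effort cost
#'
#' Volume-weighted cubed neural excitations,
#' `J_mus = W_mus/(N N_mus) sum_k sum_i (w_i / sum_j w_j) n_e,i^3`.
#'
#' @param excitations N x n_mus matrix in `[0, 1]`.
#' @param model an `msk_model`.
#' @param weights an [objective_weights()] object.
#' @return scalar cost.
#' @export
muscular_effort_cost <- function(excitations, model, weights) {
  nm <- n_mus(model)
  if (nm == 0) return(0)
  ex <- matrix(as.matrix(excitations), ncol = nm)
  if (any(ex < 0))
    stop("negative neural excitation: cubed effort would reward co-excitation")
  wn <- model$muscles$w / sum(model$muscles$w)
  weights$W_mus / (nrow(ex) * nm) * sum(sweep(ex^3, 2, wn, "*"))
}

#' Torque effort cost
#'
#' `J_tor = W_tor/(N N_tor) sum_k sum_i m_i^2`.
#'
#' @param torques N x n_tor matrix (N m).
#' @param weights an [objective_weights()] object.
#' @return scalar cost.
#' @export
torque_effort_cost <- function(torques, weights) {
  m <- as.matrix(torques)
  if (length(m) == 0) return(0)
  weights$W_tor / (nrow(m) * ncol(m)) * sum(m^2)
}

#' Regularization cost
#'
#' Penalizes the temporal derivative of states and controls,
#' `J_reg = W_reg (N-1) / (T^2 (N_states + N_controls)) *
#'  sum_k (|x[k+1]-x[k]|^2 + |u[k+1]-u[k]|^2)`.
#'
#' @param traj an [msk_trajectory()].
#' @param weights an [objective_weights()] object.
#' @return scalar cost.
#' @export
regularization_cost <- function(traj, weights) {
  N <- traj$N
  dx <- diff(traj$X); du <- diff(traj$U)
  weights$W_reg * (N - 1) / (traj$T^2 * (ncol(traj$X) + ncol(traj$U))) *
    (sum(dx^2) + sum(du^2))
}

#' Collocation dynamics constraints
#'
#' Stacked equality residuals of the transcription: backward-Euler residuals
#' `f(x[k+1], (x[k+1]-x[k])/h, u[k+1])` for every interval, plus the
#' first-node forward-Euler closure `f(x[1], (x[2]-x[1])/h, u[1])` with the
#' kinematic-identity rows of the six global pelvis coordinates removed so
#' global motion is not restricted. No initial-state, periodicity or task
#' constraint is imposed anywhere.
#'
#' @param traj an [msk_trajectory()].
#' @param model an `msk_model`.
#' @return residual vector of length `(N-1) * n_residual + n_residual - 6`.
#' @export
dynamics_constraints <- function(traj, model) {
  if (traj$N < 2) stop("need at least 2 nodes")
  cpp_traj_residual(model_for_cpp(model), traj$X, traj$U, traj$h)
}
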
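# Direct-collocation transcription and the two solvers built on it:
# motion reconstruction (marker or coordinate tracking) and static standing
# calibration of the ground contact geometry.

# variable layout: node-major, per node [x (nx); u (nu)]
ocp_layout <- function(model, N) {
  nx <- n_states(model); nu <- n_controls(model)
  list(N = N, nx = nx, nu = nu, nv = nx + nu, nz = N * (nx + nu))
}

z_to_XU <- function(z, lay) {
  M <- matrix(z, nrow = lay$nv)
  list(X = t(M[seq_len(lay$nx), , drop = FALSE]),
       U = t(M[lay$nx + seq_len(lay$nu), , drop = FALSE]))
}

XU_to_z <- function(X, U) as.vector(t(cbind(X, U)))

# bounds, scales and constraint row scales per node
ocp_bounds <- function(model, lay, fix_qdot = FALSE) {
  nd <- n_dof(model); nm <- n_mus(model); nt <- n_tor(model)
  qlo <- model$ranges[, 1]; qhi <- model$ranges[, 2]
  vlim <- if (fix_qdot) 0 else 50
  lo1 <- c(qlo, rep(-vlim, nd), rep(0, nm), rep(0.2, nm), rep(0, nm), rep(-1.5, nt))
  hi1 <- c(qhi, rep(vlim, nd), rep(1, nm), rep(2.2, nm), rep(1, nm), rep(1.5, nt))
  list(lower = rep(lo1, lay$N), upper = rep(hi1, lay$N))
}

ocp_zscale <- function(model, lay) {
  nd <- n_dof(model); nm <- n_mus(model); nt <- n_tor(model)
  rep(c(rep(1, nd), rep(10, nd), rep(1, 2 * nm), rep(1, nm), rep(1, nt)), lay$N)
}

dyn_row_scale <- function(model) {
  nd <- n_dof(model); nm <- n_mus(model)
  bw <- model$body_mass * 9.81
  c(rep(10, nd), rep(bw, 3), rep(0.5 * bw, nd - 3), rep(20, nm), rep(1, nm))
}

# Predicted tracking signals (in tracking units) for a state matrix.
predicted_signals <- function(model, X, type_names, pred = NULL) {
  nd <- n_dof(model)
  bw <- model$body_mass * 9.81
  if (is.null(pred)) pred <- cpp_predicted(model_for_cpp(model), X, FALSE)
  out <- list()
  for (j in type_names) {
    out[[j]] <- switch(j,
      translation = 1000 * X[, 1:3, drop = FALSE],
      angle = (180 / pi) * X[, 4:nd, drop = FALSE],
      marker = 1000 * pred$markers,
      grf = (100 / bw) * pred$grf,
      stop(sprintf("unknown tracking type '%s'", j)))
  }
  out
}

# Objective closure for the collocation NLP: tracking + muscular effort +
# torque effort + regularization, with analytic gradient and a Gauss-Newton
# Hessian (exact for the quadratic terms).
make_ocp_objective <- function(model, data, weights, T, lay) {
  nd <- n_dof(model); nm <- n_mus(model); nt <- n_tor(model)
  nx <- lay$nx; nu <- lay$nu; nv <- lay$nv; N <- lay$N
  bw <- model$body_mass * 9.81
  types <- names(data$types)
  for (j in types)
    if (!j %in% names(weights$W_tra))
      stop(sprintf("no tracking weight configured for data type '%s'", j))
  wn <- if (nm) model$muscles$w / sum(model$muscles$w) else numeric(0)
  creg <- weights$W_reg * (N - 1) / (T^2 * (nx + nu))
  # constant regularization Hessian: 2*creg * chain Laplacian per variable
  H_reg <- NULL
  if (creg > 0) {
    ii <- jj <- integer(0); vv <- numeric(0)
    for (k in seq_len(N - 1)) {
      a <- (k - 1) * nv + seq_len(nv); b <- k * nv + seq_len(nv)
      ii <- c(ii, a, b, a, b); jj <- c(jj, a, b, b, a)
      vv <- c(vv, rep(2 * creg, 2 * nv), rep(-2 * creg, 2 * nv))
    }
    H_reg <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(lay$nz, lay$nz))
  }
  xb <- if ("grf" %in% types) 2 * nd else nd  # size of the dense state block
  blk_rows <- unlist(lapply(seq_len(N), function(k) rep((k - 1) * nv + seq_len(xb), xb)))
  blk_cols <- unlist(lapply(seq_len(N), function(k) rep((k - 1) * nv + seq_len(xb), each = xb)))
  u_idx <- as.vector(vapply(seq_len(N),
                            function(k) as.integer((k - 1) * nv + nx + seq_len(nu)),
                            integer(nu)))

  function(z, derivs) {
    XU <- z_to_XU(z, lay)
    X <- XU$X; U <- XU$U
    pred <- cpp_predicted(model_for_cpp(model), X, derivs)
    yhat <- predicted_signals(model, X, types, pred)
    J_tra <- 0
    res <- list()
    for (j in types) {
      ty <- data$types[[j]]
      r <- yhat[[j]] - ty$y
      r[!ty$mask] <- 0
      res[[j]] <- r
      J_tra <- J_tra + weights$W_tra[[j]] / (N * ncol(ty$y)) * sum(r^2)
    }
    ne <- if (nm) U[, seq_len(nm), drop = FALSE] else NULL
    tq <- if (nt) U[, nm + seq_len(nt), drop = FALSE] else NULL
    J_mus <- if (nm) weights$W_mus / (N * nm) * sum(sweep(pmax(ne, 0)^3, 2, wn, "*")) else 0
    J_tor <- if (nt) weights$W_tor / (N * nt) * sum(tq^2) else 0
    J_reg <- if (creg > 0) creg * (sum(diff(X)^2) + sum(diff(U)^2)) else 0
    J <- J_tra + J_mus + J_tor + J_reg
    out <- list(J = J, breakdown = c(tracking = J_tra, muscular_effort = J_mus,
                                     torque_effort = J_tor, regularization = J_reg))
    if (!derivs) return(out)
    grad <- numeric(lay$nz)
    Bv <- array(0, c(xb, xb, N))  # per-node GN state blocks
    for (j in types) {
      ty <- data$types[[j]]
      fj <- 2 * weights$W_tra[[j]] / (N * ncol(ty$y))
      if (j == "translation") {
        sc <- 1000
        for (i in 1:3) {
          grad[(seq_len(N) - 1) * nv + i] <- grad[(seq_len(N) - 1) * nv + i] +
            fj * sc * res[[j]][, i]
          for (k in seq_len(N)) Bv[i, i, k] <- Bv[i, i, k] + fj * sc^2
        }
      } else if (j == "angle") {
        sc <- 180 / pi
        for (i in seq_len(nd - 3)) {
          col <- 3 + i
          grad[(seq_len(N) - 1) * nv + col] <- grad[(seq_len(N) - 1) * nv + col] +
            fj * sc * res[[j]][, i]
          for (k in seq_len(N)) Bv[col, col, k] <- Bv[col, col, k] + fj * sc^2
        }
      } else if (j == "marker") {
        nmk <- ncol(ty$y)
        dmk <- array(pred$dmarkers, c(nmk, nd, N))
        for (k in seq_len(N)) {
          G <- 1000 * dmk[, , k]
          mk_mask <- ty$mask[k, ]
          if (!all(mk_mask)) G[!mk_mask, ] <- 0
          grad[(k - 1) * nv + seq_len(nd)] <- grad[(k - 1) * nv + seq_len(nd)] +
            fj * as.vector(crossprod(G, res[[j]][k, ]))
          Bv[seq_len(nd), seq_len(nd), k] <- Bv[seq_len(nd), seq_len(nd), k] +
            fj * crossprod(G)
        }
      } else if (j == "grf") {
        dgr <- array(pred$dgrf, c(6, 2 * nd, N))
        for (k in seq_len(N)) {
          G <- (100 / bw) * dgr[, , k]
          grad[(k - 1) * nv + seq_len(2 * nd)] <- grad[(k - 1) * nv + seq_len(2 * nd)] +
            fj * as.vector(crossprod(G, res[[j]][k, ]))
          Bv[seq_len(2 * nd), seq_len(2 * nd), k] <-
            Bv[seq_len(2 * nd), seq_len(2 * nd), k] + fj * crossprod(G)
        }
      }
    }
    u_hess <- numeric(N * nu)
    if (nm) {
      cm <- weights$W_mus / (N * nm)
      gne <- 3 * cm * sweep(pmax(ne, 0)^2, 2, wn, "*")
      hne <- 6 * cm * sweep(pmax(ne, 0), 2, wn, "*")
      for (i in seq_len(nm)) {
        grad[(seq_len(N) - 1) * nv + nx + i] <- grad[(seq_len(N) - 1) * nv + nx + i] + gne[, i]
        u_hess[(seq_len(N) - 1) * nu + i] <- hne[, i]
      }
    }
    if (nt) {
      ct <- weights$W_tor / (N * nt)
      for (i in seq_len(nt)) {
        grad[(seq_len(N) - 1) * nv + nx + nm + i] <-
          grad[(seq_len(N) - 1) * nv + nx + nm + i] + 2 * ct * tq[, i]
        u_hess[(seq_len(N) - 1) * nu + nm + i] <- 2 * ct
      }
    }
    H <- Matrix::sparseMatrix(i = c(blk_rows, u_idx), j = c(blk_cols, u_idx),
                              x = c(as.vector(Bv), u_hess),
                              dims = c(lay$nz, lay$nz))
    if (creg > 0) {
      H <- H + H_reg
      grad <- grad + as.vector(H_reg %*% z)
    }
    out$grad <- grad
    out$hess <- H
    out
  }
}

make_ocp_constraints <- function(model, lay, h) {
  nf <- n_residual(model)
  nr <- (lay$N - 1) * nf + nf - 6
  function(z, derivs) {
    XU <- z_to_XU(z, lay)
    cc <- cpp_traj_residual(model_for_cpp(model), XU$X, XU$U, h)
    out <- list(c = cc)
    if (derivs) {
      tr <- cpp_traj_jacobian(model_for_cpp(model), XU$X, XU$U, h)
      out$A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v,
                                    dims = c(nr, lay$nz))
    }
    out
  }
}

#' Prepend context samples before the motion of interest
#'
#' The first-node closure of the transcription assumes constant state and
#' control velocity between the first two nodes, which slightly influences
#' the solution there. To keep that edge effect out of the analyzed span,
#' reconstruction data include lead-in samples before the motion of interest
#' (10 by default).
#'
#' @param data a [tracking_data()] whose `moi` marks the motion of interest
#'   within the full recording span.
#' @param n_pre number of context samples before the motion of interest.
#' @return a [tracking_data()] spanning `[moi_start - n_pre, moi_end)`, with
#'   `moi` updated to the new indexing.
#' @export
prepend_context <- function(data, n_pre = 10) {
  stopifnot(n_pre >= 0)
  start <- data$moi[1] - n_pre
  if (start < 1)
    stop(sprintf("recording too short: %d lead-in samples available, %d requested",
                 data$moi[1] - 1, n_pre))
  rows <- seq(start, data$moi[2] - 1)
  types <- lapply(data$types, function(ty)
    list(y = ty$y[rows, , drop = FALSE], mask = ty$mask[rows, , drop = FALSE],
         unit = ty$unit))
  tracking_data(types, rate = data$rate,
                moi = c(n_pre + 1L, length(rows) + 1L))
}

#' Reconstruct a measured motion as an optimal control simulation
#'
#' Transcribes the tracking problem with direct collocation (one node per
#' data sample, backward-Euler dynamics, first-node forward-Euler closure)
#' and solves the resulting sparse NLP. In marker mode the objective tracks
#' measured marker positions and ground reaction forces; in coordinate mode
#' it tracks pelvis translations, angles (from inverse kinematics) and ground
#' reaction forces. Reference data are used unfiltered: the simulation itself
#' acts as a physical filter through the model dynamics and effort terms.
#'
#' The problem is solved over a progressively growing time window (the
#' standing-based initial guess matches the lead-in data, so each extension
#' is a small warm-started perturbation), followed by a full-horizon polish.
#' Besides the KKT test, the solver stops once the objective has been flat
#' at a feasible point for a stretch of iterations (status
#' `"stalled_progress"`); such results are feasible to `constraint_tol` and
#' flagged as converged.
#'
#' @param model an `msk_model` (contact offset already calibrated).
#' @param data a [tracking_data()] including context samples
#'   (see [prepend_context()]).
#' @param mode `"marker"` or `"coordinate"`.
#' @param weights objective weights; defaults to the running weights of the
#'   chosen mode.
#' @param settings a [solver_settings()].
#' @param initial_guess an `msk_standing` result (tiled over all nodes) or an
#'   [msk_trajectory()].
#' @return an object of class `msk_recon` with the solved trajectory,
#'   objective breakdown, maximum dynamics-constraint violation and a
#'   convergence report.
#' @export
solve_reconstruction <- function(model, data, mode = c("marker", "coordinate"),
                                 weights = NULL, settings = solver_settings(),
                                 initial_guess) {
  mode <- match.arg(mode)
  if (is.null(weights)) weights <- objective_weights(mode, "running")
  need <- if (mode == "marker") c("marker", "grf") else c("translation", "angle", "grf")
  missing_ty <- setdiff(need, names(data$types))
  if (length(missing_ty))
    stop(sprintf("%s tracking needs data types: %s", mode,
                 paste(missing_ty, collapse = ", ")))
  data <- data[c("types", "N", "rate", "times", "moi")]
  class(data) <- "tracking_data"
  data$types <- data$types[need]
  N <- data$N
  T <- (N - 1) / data$rate
  h <- 1 / data$rate
  lay <- ocp_layout(model, N)
  if (inherits(initial_guess, "msk_standing")) {
    X0 <- matrix(initial_guess$x, N, lay$nx, byrow = TRUE)
    U0 <- matrix(initial_guess$u, N, lay$nu, byrow = TRUE)
    model$contacts$offset <- initial_guess$offset
  } else if (inherits(initial_guess, "msk_trajectory")) {
    X0 <- initial_guess$X; U0 <- initial_guess$U
    if (nrow(X0) != N) stop("initial guess node count does not match the data")
  } else stop("initial_guess must be an msk_standing or msk_trajectory object")
  nf <- n_residual(model)
  rs <- dyn_row_scale(model)
  # progressive horizon growth: the lead-in data start near the standing
  # pose, so solving an expanding time window -- each stage warm-started from
  # the previous solution with the last state tiled over the new nodes --
  # follows the natural homotopy of the recording and keeps every stage
  # inside the Newton region
  grow <- 10L
  window <- 25L  # nodes left free behind the growing front
  stages <- unique(c(seq(min(grow, N), N, by = grow), N))
  plan_K <- c(stages, N)
  plan_polish <- c(rep(FALSE, length(stages)), TRUE)
  X <- X0; U <- U0
  iters_total <- 0L; wall_total <- 0; cpu_total <- 0; nlp_total <- 0
  sol <- NULL
  for (si in seq_along(plan_K)) {
    K <- plan_K[si]
    layK <- ocp_layout(model, K)
    dataK <- truncate_tracking_data(data, K)
    TK <- (K - 1) / data$rate
    objK <- make_ocp_objective(model, dataK, weights, TK, layK)
    conK <- make_ocp_constraints(model, layK, h)
    bndK <- ocp_bounds(model, layK)
    cscaleK <- c(rep(rs, K - 1), rs[7:nf])
    zK <- XU_to_z(X[seq_len(K), , drop = FALSE], U[seq_len(K), , drop = FALSE])
    setK <- settings
    if (!plan_polish[si]) {
      # growth stage: freeze the nodes behind the window so only the fresh
      # tail is optimized; the closing polish then frees the full horizon
      frozen_nodes <- seq_len(max(0, K - window))
      if (length(frozen_nodes)) {
        idx <- as.vector(vapply(frozen_nodes, function(k)
          as.integer((k - 1) * layK$nv + seq_len(layK$nv)), integer(layK$nv)))
        bndK$lower[idx] <- zK[idx]
        bndK$upper[idx] <- zK[idx]
      }
      setK$tol <- max(settings$tol, 1e-3)
      setK$max_iterations <- min(settings$max_iterations, 150)
    }
    sol <- sqp_solve(zK, objK, conK, bndK$lower, bndK$upper,
                     ocp_zscale(model, layK), cscaleK, setK,
                     quiet = !isTRUE(settings$verbose),
                     structure = if (K >= 3) kkt_block_structure(K, layK$nv, nf))
    XUK <- z_to_XU(sol$z, layK)
    X[seq_len(K), ] <- XUK$X
    U[seq_len(K), ] <- XUK$U
    if (K < N) {
      ext <- seq(K + 1, min(K + grow, N))
      X[ext, ] <- matrix(X[K, ], length(ext), layK$nx, byrow = TRUE)
      U[ext, ] <- matrix(U[K, ], length(ext), layK$nu, byrow = TRUE)
    }
    iters_total <- iters_total + sol$iterations
    wall_total <- wall_total + sol$wall_time_s
    cpu_total <- cpu_total + sol$cpu_time_s
    nlp_total <- nlp_total + sol$nlp_cpu_s
  }
  sol$iterations <- iters_total
  sol$wall_time_s <- wall_total
  sol$cpu_time_s <- cpu_total
  sol$nlp_eval_share_pct <- if (cpu_total > 0) 100 * nlp_total / cpu_total else NA_real_
  XU <- z_to_XU(sol$z, lay)
  traj <- msk_trajectory(model, XU$X, XU$U, T)
  ok <- sol$status %in% c("converged", "stalled_progress") &&
    sol$max_violation <= settings$constraint_tol
  if (!ok)
    warning(sprintf("reconstruction did not converge (%s) after %d iterations",
                    sol$status, sol$iterations))
  structure(list(
    trajectory = traj, mode = mode, objective = sol$objective,
    breakdown = sol$breakdown, max_violation = sol$max_violation,
    converged = ok,
    convergence = list(status = sol$status, iterations = sol$iterations,
                       scaled_nlp_error = sol$scaled_nlp_error,
                       wall_time_s = sol$wall_time_s, cpu_time_s = sol$cpu_time_s,
                       cpu_per_iteration_s = sol$cpu_time_s / max(1, sol$iterations),
                       nlp_eval_share_pct = sol$nlp_eval_share_pct),
    model = model, data = data, weights = weights, settings = settings),
    class = "msk_recon")
}

#' Simulate static standing and calibrate the contact geometry
#'
#' Solves a single-node optimal control problem that tracks one time point of
#' static (N-pose) kinematic and ground reaction force data. Static
#' equilibrium is enforced through `f(x, 0, u) = 0` (velocities and
#' accelerations zero) and the vertical offset of the ground contact points
#' is a free optimization variable, which absorbs, for example, shoe sole
#' thickness. The problem is solved from `settings$restarts` random initial
#' guesses and the solution with the lowest objective is returned (ties go to
#' the lowest restart index). The regularization term is omitted.
#'
#' @param model an `msk_model`.
#' @param static_data a [tracking_data()] with a single node (marker or
#'   coordinate types plus `grf`).
#' @param mode `"marker"` or `"coordinate"`; default inferred from the data.
#' @param weights objective weights; defaults to the standing weights.
#' @param settings a [solver_settings()]; `restarts` and `seed` control the
#'   random initialization.
#' @return an object of class `msk_standing` with the equilibrium state `x`,
#'   controls `u`, calibrated vertical contact `offset` (m), the calibrated
#'   model (`model`), objective breakdown and per-restart diagnostics.
#' @export
solve_standing <- function(model, static_data, mode = NULL, weights = NULL,
                           settings = solver_settings()) {
  if (static_data$N != 1) stop("static standing data must contain exactly one node")
  if (is.null(mode))
    mode <- if ("marker" %in% names(static_data$types)) "marker" else "coordinate"
  if (is.null(weights)) weights <- objective_weights(mode, "standing")
  need <- if (mode == "marker") c("marker", "grf") else c("translation", "angle", "grf")
  static_data$types <- static_data$types[need]
  nd <- n_dof(model); nm <- n_mus(model); nt <- n_tor(model)
  nx <- n_states(model); nu <- n_controls(model); nf <- n_residual(model)
  nz <- nx + nu + 1
  ioff <- nz
  bw <- model$body_mass * 9.81
  types <- names(static_data$types)
  set_offset <- function(m, z) { m$contacts$offset <- z[ioff]; m }

  yhat_fn <- function(z) {
    m2 <- set_offset(model, z)
    X <- matrix(z[seq_len(nx)], 1)
    predicted_signals(m2, X, types)
  }
  obj <- function(z, derivs) {
    yhat <- yhat_fn(z)
    J_tra <- 0; res <- list()
    for (j in types) {
      ty <- static_data$types[[j]]
      r <- yhat[[j]] - ty$y; r[!ty$mask] <- 0
      res[[j]] <- as.vector(r)
      J_tra <- J_tra + weights$W_tra[[j]] / ncol(ty$y) * sum(r^2)
    }
    ne <- z[nx + seq_len(nm)]; tq <- z[nx + nm + seq_len(nt)]
    wn <- if (nm) model$muscles$w / sum(model$muscles$w) else numeric(0)
    J_mus <- if (nm) weights$W_mus / nm * sum(wn * pmax(ne, 0)^3) else 0
    J_tor <- if (nt) weights$W_tor / nt * sum(tq^2) else 0
    out <- list(J = J_tra + J_mus + J_tor,
                breakdown = c(tracking = J_tra, muscular_effort = J_mus,
                              torque_effort = J_tor, regularization = 0))
    if (!derivs) return(out)
    grad <- numeric(nz); H <- matrix(0, nz, nz)
    stacked <- function(z) {
      yh <- yhat_fn(z)
      unlist(lapply(types, function(j) as.vector(yh[[j]])))
    }
    G <- fd_jac(stacked, z, 1e-6)
    r0 <- 0
    for (j in types) {
      ty <- static_data$types[[j]]
      rows <- r0 + seq_len(ncol(ty$y)); r0 <- r0 + ncol(ty$y)
      Gj <- G[rows, , drop = FALSE]
      Gj[!as.vector(ty$mask), ] <- 0
      fj <- 2 * weights$W_tra[[j]] / ncol(ty$y)
      grad <- grad + fj * as.vector(crossprod(Gj, res[[j]]))
      H <- H + fj * crossprod(Gj)
    }
    if (nm) {
      wn3 <- weights$W_mus / nm * (model$muscles$w / sum(model$muscles$w))
      idx <- nx + seq_len(nm)
      grad[idx] <- grad[idx] + 3 * wn3 * pmax(z[idx], 0)^2
      diag(H)[idx] <- diag(H)[idx] + 6 * wn3 * pmax(z[idx], 0)
    }
    if (nt) {
      idx <- nx + nm + seq_len(nt)
      grad[idx] <- grad[idx] + 2 * weights$W_tor / nt * z[idx]
      diag(H)[idx] <- diag(H)[idx] + 2 * weights$W_tor / nt
    }
    out$grad <- grad
    out$hess <- Matrix::Matrix(H, sparse = TRUE)
    out
  }
  con_raw <- function(z) {
    m2 <- set_offset(model, z)
    cpp_dyn_residual(m2, z[seq_len(nx)], rep(0, nx), z[nx + seq_len(nu)])
  }
  con <- function(z, derivs) {
    out <- list(c = con_raw(z))
    if (derivs) out$A <- Matrix::Matrix(fd_jac(con_raw, z, 1e-6), sparse = TRUE)
    out
  }
  lay1 <- ocp_layout(model, 1)
  bnd <- ocp_bounds(model, lay1, fix_qdot = TRUE)
  lower <- c(bnd$lower, -0.05); upper <- c(bnd$upper, 0.05)
  zscale <- c(ocp_zscale(model, lay1), 0.01)
  cscale <- dyn_row_scale(model)
  # data-informed center for the random global-translation guesses
  center <- if (mode == "marker") {
    mk <- matrix(static_data$types$marker$y[1, ], ncol = 3, byrow = TRUE) / 1000
    c(mean(mk[, 1]), 0.95, mean(mk[, 3]))
  } else {
    tr <- static_data$types$translation$y[1, ] / 1000
    c(tr[1], tr[2], tr[3])
  }
  set.seed(settings$seed)
  runs <- vector("list", settings$restarts)
  for (r in seq_len(settings$restarts)) {
    q0 <- c(center + stats::runif(3, -0.2, 0.2) * c(1, 0.5, 1),
            stats::runif(3, -0.5, 0.5),
            stats::runif(nd - 6, pmax(model$ranges[7:nd, 1], -1.2),
                         pmin(model$ranges[7:nd, 2], 1.2)))
    # pose prefit: a few unconstrained Gauss-Newton steps on the kinematic
    # tracking term pull the random draw toward the data basin; the restarts
    # keep their diversity in the remaining variables and in the prefit's
    # own local minima
    if (mode == "marker") {
      y_m <- static_data$types$marker$y[1, ] / 1000
      for (it in 1:15) {
        rm_ <- y_m - as.vector(t(cpp_markers(model_for_cpp(model), q0)))
        G <- cpp_marker_jac(model_for_cpp(model), q0)
        step <- tryCatch(solve(crossprod(G) + diag(1e-8, nd),
                               crossprod(G, rm_))[, 1], error = function(e) NULL)
        if (is.null(step)) break
        q0 <- pmin(pmax(q0 + step, model$ranges[, 1]), model$ranges[, 2])
        if (max(abs(step)) < 1e-10) break
      }
    } else {
      q0 <- c(static_data$types$translation$y[1, ] / 1000,
              static_data$types$angle$y[1, ] * pi / 180)
    }
    # fiber lengths near tendon-slack consistency with the drawn pose: the
    # exponential tendon force makes far-off draws numerically useless
    s0 <- if (nm) pmin(pmax((muscle_geometry(model, q0)$lmt - model$muscles$ltslack) /
                              model$muscles$lmopt +
                              stats::runif(nm, -0.05, 0.05), 0.3), 1.8) else numeric(0)
    z0 <- c(q0, rep(0, nd), stats::runif(nm, 0, 0.3), s0,
            stats::runif(nm, 0, 0.3), stats::runif(nt, 0, 0.3),
            stats::runif(1, -0.02, 0.02))
    st_settings <- settings
    st_settings$max_iterations <- min(settings$max_iterations, 500)
    runs[[r]] <- sqp_solve(z0, obj, con, lower, upper, zscale, cscale, st_settings)
  }
  ok <- vapply(runs, function(s) s$status == "converged", logical(1))
  if (!any(ok))
    stop("standing calibration failed in all restarts: ",
         paste(sprintf("#%d %s", seq_along(runs),
                       vapply(runs, `[[`, "", "status")), collapse = ", "))
  objs <- vapply(runs, function(s) if (s$status == "converged") s$objective else Inf,
                 numeric(1))
  best <- which.min(objs)  # which.min returns the first (lowest index) tie
  sol <- runs[[best]]
  model_cal <- model
  model_cal$contacts$offset <- sol$z[ioff]
  structure(list(
    x = sol$z[seq_len(nx)], u = sol$z[nx + seq_len(nu)], offset = sol$z[ioff],
    objective = sol$objective, breakdown = sol$breakdown,
    max_violation = sol$max_violation, mode = mode,
    convergence = list(status = sol$status, iterations = sol$iterations,
                       scaled_nlp_error = sol$scaled_nlp_error,
                       wall_time_s = sol$wall_time_s, cpu_time_s = sol$cpu_time_s,
                       nlp_eval_share_pct = sol$nlp_eval_share_pct),
    restarts = list(seed = settings$seed, n = settings$restarts,
                    objective = objs, status = vapply(runs, `[[`, "", "status"),
                    selected = best),
    model = model_cal, data = static_data, weights = weights),
    class = "msk_standing")
}

truncate_tracking_data <- function(data, K) {
  types <- lapply(data$types, function(ty)
    list(y = ty$y[seq_len(K), , drop = FALSE],
         mask = ty$mask[seq_len(K), , drop = FALSE], unit = ty$unit))
  tracking_data(types, rate = data$rate, moi = c(1L, K + 1L))
}

# central finite-difference Jacobian
fd_jac <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    d <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + d
    xm <- x; xm[i] <- x[i] - d
    J[, i] <- (f(xp) - f(xm)) / (2 * d)
  }
  J
}
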
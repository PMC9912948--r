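# Baseline inverse pipeline: per-frame weighted-least-squares inverse
# kinematics, dual-pass Butterworth filtering, and inverse dynamics with
# pelvis residual forces and moments.

#' Inverse kinematics
#'
#' Per-frame weighted least squares: for every frame, the coordinates q
#' minimize `sum_m w_m ||measured_m - modeled_m(q)||^2` over the visible
#' markers. Frames are solved independently (no temporal coupling); by
#' default each frame is warm-started from the previous solution, which does
#' not change the optimum but speeds up convergence. Set `warm_start = FALSE`
#' to restart every frame from `q_init`.
#'
#' @param markers a [marker_recording()] whose marker names match the model's
#'   (any order).
#' @param model an `msk_model`.
#' @param marker_weights per-marker weights; all equal by default.
#' @param q_init initial coordinate vector for the first frame (and for all
#'   frames when `warm_start = FALSE`).
#' @param warm_start warm-start each frame from the previous solution.
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance.
#' @return object of class `msk_ik` with coordinates `Q` (frames x n_dof,
#'   rad/m), per-frame marker residual RMS (`resid_rms_mm`) and the weights
#'   used.
#' @export
inverse_kinematics <- function(markers, model, marker_weights = NULL,
                               q_init = NULL, warm_start = TRUE,
                               max_iter = 100, tol = 1e-12) {
  ord <- match(model$markers$name, markers$names)
  if (anyNA(ord))
    stop("marker recording is missing model markers: ",
         paste(model$markers$name[is.na(ord)], collapse = ", "))
  nmk <- length(ord)
  nd <- n_dof(model)
  if (is.null(marker_weights)) marker_weights <- rep(1, nmk)
  stopifnot(length(marker_weights) == nmk, all(marker_weights >= 0))
  n <- nrow(markers$pos)
  cols <- as.vector(t(outer(ord - 1, 1:3, function(a, b) 3 * a + b)))
  meas <- markers$pos[, cols, drop = FALSE] / 1000  # m, model marker order
  vis <- markers$mask[, ord, drop = FALSE]
  if (is.null(q_init)) {
    q_init <- rep(0, nd)
    q_init[2] <- 1
    pel <- which(model$markers$dof <= 6)
    if (length(pel) >= 1) {
      cen <- colMeans(matrix(meas[1, as.vector(t(outer(3 * (pel - 1), 1:3, `+`)))],
                             ncol = 3, byrow = TRUE), na.rm = TRUE)
      q_init[1] <- cen[1]; q_init[3] <- cen[3]
    }
  }
  Q <- matrix(0, n, nd)
  rms <- numeric(n)
  w3 <- rep(marker_weights, each = 3)
  q <- q_init
  for (k in seq_len(n)) {
    if (!warm_start) q <- q_init
    mk_vis <- vis[k, ]
    if (sum(mk_vis) < 3)
      stop(sprintf("frame %d is under-determined: %d visible markers",
                   k, sum(mk_vis)))
    rows <- rep(mk_vis, each = 3)
    y <- meas[k, rows]
    wr <- w3[rows]
    for (it in seq_len(max_iter)) {
      mod <- as.vector(t(cpp_markers(model_for_cpp(model), q)))[rows]
      J <- cpp_marker_jac(model_for_cpp(model), q)[rows, , drop = FALSE]
      r <- y - mod
      A <- crossprod(J * sqrt(wr)) + diag(1e-10, nd)
      g <- as.vector(crossprod(J, wr * r))
      step <- tryCatch(solve(A, g), error = function(e) NULL)
      if (is.null(step))
        stop(sprintf("frame %d is under-determined (singular normal equations)", k))
      sse0 <- sum(wr * r^2)
      alpha <- 1
      repeat {
        qt <- q + alpha * step
        rt <- y - as.vector(t(cpp_markers(model_for_cpp(model), qt)))[rows]
        if (sum(wr * rt^2) <= sse0 || alpha < 1e-8) break
        alpha <- alpha / 2
      }
      q <- q + alpha * step
      if (max(abs(alpha * step)) < tol) break
    }
    Q[k, ] <- q
    mod <- as.vector(t(cpp_markers(model_for_cpp(model), q)))[rows]
    rms[k] <- 1000 * sqrt(mean((y - mod)^2))
  }
  structure(list(Q = Q, resid_rms_mm = rms, weights = marker_weights,
                 rate = markers$rate),
            class = "msk_ik")
}

#' Dual-pass low-pass Butterworth filter
#'
#' Forward-backward (zero phase) Butterworth low-pass; defaults match the
#' inverse-dynamics pathway: 3rd order, 15 Hz cutoff. The nominal cutoff is
#' applied per pass without -3 dB compensation (common biomechanics
#' practice); set `correct_cutoff = TRUE` to compensate for the double pass.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param cutoff_hz cutoff frequency (Hz), must be below Nyquist.
#' @param rate sampling rate (Hz).
#' @param order filter order per pass.
#' @param correct_cutoff apply the dual-pass cutoff correction factor.
#' @return filtered series, same shape as `x`.
#' @export
butterworth_dualpass <- function(x, cutoff_hz, rate, order = 3,
                                 correct_cutoff = FALSE) {
  if (cutoff_hz >= rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, rate / 2))
  wc <- cutoff_hz
  if (correct_cutoff) wc <- cutoff_hz / (2^(1 / (2 * order)) - 1)^0.25
  if (wc >= rate / 2) wc <- 0.999 * rate / 2
  bf <- signal::butter(order, wc / (rate / 2), type = "low")
  filt1 <- function(v) {
    # explicit forward-backward pass with odd-reflection padding: the IIR
    # start-up transients decay inside the padding at both ends
    n <- length(v)
    pad <- min(n - 1, ceiling(6 * rate / cutoff_hz))
    ext <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    y <- as.numeric(signal::filter(bf, ext))
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
    y[pad + seq_len(n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

# 2nd-order differences: central in the interior, one-sided 3-point at edges.
fd_diff <- function(x, rate) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- x * 0
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / 2
  d[1, ] <- (-3 * x[1, ] + 4 * x[2, ] - x[3, ]) / 2
  d[n, ] <- (3 * x[n, ] - 4 * x[n - 1, ] + x[n - 2, ]) / 2
  d * rate
}

#' Inverse dynamics
#'
#' Joint moments from recursive Newton-Euler dynamics with the measured
#' ground reaction forces applied as external loads at their centers of
#' pressure. Velocities and accelerations are obtained by 2nd-order central
#' differences (one-sided at the edges). The 6-DoF force/moment imbalance at
#' the pelvis is reported as residual forces (N) and moments (N m), not
#' zeroed. Coordinates and forces are expected time-aligned at the same rate
#' and filtered with the same settings (see [butterworth_dualpass()]);
#' filtering is the caller's responsibility and the settings used are only
#' recorded here.
#'
#' @param model an `msk_model`.
#' @param coordinates N x n_dof matrix of generalized coordinates (m / rad).
#' @param grf a [forceplate_recording()] at the same rate, plate 1 = right
#'   foot, plate 2 = left foot.
#' @param rate sampling rate (Hz).
#' @param filter_settings optional list recorded in the result.
#' @return object of class `msk_id` with `joint_moments` (N m),
#'   `residual_forces`, `residual_moments` at the pelvis, and the settings.
#' @export
inverse_dynamics <- function(model, coordinates, grf, rate,
                             filter_settings = NULL) {
  Q <- as.matrix(coordinates)
  nd <- n_dof(model)
  if (ncol(Q) != nd) stop("coordinate matrix does not match the model DoFs")
  n <- nrow(Q)
  if (nrow(grf$plates[[1]]$force) != n)
    stop(sprintf("misaligned series: %d coordinate frames vs %d force frames",
                 n, nrow(grf$plates[[1]]$force)))
  if (abs(grf$rate - rate) > 1e-9)
    stop("GRF rate differs from the coordinate rate")
  QD <- fd_diff(Q, rate)
  QDD <- fd_diff(QD, rate)
  feet <- list(right = model$contacts$dof[model$contacts$foot == 0][1],
               left = model$contacts$dof[model$contacts$foot == 1][1])
  ext <- list(
    list(dof = feet$right, force = grf$plates[[1]]$force,
         point = grf$plates[[1]]$cop, moment = grf$plates[[1]]$moment),
    list(dof = feet$left, force = grf$plates[[2]]$force,
         point = grf$plates[[2]]$cop, moment = grf$plates[[2]]$moment))
  gen <- cpp_inverse_dynamics(model_for_cpp(model), Q, QD, QDD, ext)
  colnames(gen) <- model$dof$name
  structure(list(joint_moments = gen[, 7:nd, drop = FALSE],
                 residual_forces = gen[, 1:3, drop = FALSE],
                 residual_moments = gen[, 4:6, drop = FALSE],
                 rate = rate, filter_settings = filter_settings),
            class = "msk_id")
}
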
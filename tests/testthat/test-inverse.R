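# Inverse kinematics, dual-pass filtering, inverse dynamics.

make_marker_rec <- function(model, Q, rate = 175) {
  pos <- t(vapply(seq_len(nrow(Q)), function(k)
    as.vector(t(ocmotion:::cpp_markers(model, Q[k, ]))) * 1000,
    numeric(3 * length(model$markers$dof))))
  marker_recording(model$markers$name, rate, pos)
}

test_that("inverse kinematics reproduces noise-free generating coordinates", {
  m <- fix_model()
  set.seed(5)
  n <- 4
  Q <- matrix(rep(c(0.1, 1.0, -0.05, 0.2, 0.05, -0.08,
                    0.15, 0.25, -0.35, -0.1, 0.3, -0.2), each = n), n)
  Q <- Q + matrix(stats::rnorm(n * 12, 0, 0.03), n)
  rec <- make_marker_rec(m, Q)
  ik <- inverse_kinematics(rec, m)
  expect_lt(max(abs(ik$Q - Q)), 1e-6)
  expect_lt(max(ik$resid_rms_mm), 1e-3)
  expect_true(all(ik$weights == 1))  # all markers weighted equally by default
})

test_that("a noisy frame matches an independent least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  m <- fix_model()
  q_true <- c(0.1, 1.0, -0.05, 0.2, 0.05, -0.08, 0.15, 0.25, -0.35, -0.1, 0.3, -0.2)
  set.seed(11)
  meas <- ocmotion:::cpp_markers(m, q_true) + matrix(stats::rnorm(42, 0, 0.003), 14)
  rec <- marker_recording(m$markers$name, 175, matrix(as.vector(t(meas)) * 1000, 1))
  ik <- inverse_kinematics(rec, m, q_init = q_true)
  oracle <- minpack.lm::nls.lm(par = q_true, fn = function(q)
    as.vector(t(ocmotion:::cpp_markers(m, q))) - as.vector(t(meas)),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15))
  sse <- function(q) sum((as.vector(t(ocmotion:::cpp_markers(m, q))) -
                            as.vector(t(meas)))^2)
  expect_lt(abs(sse(ik$Q[1, ]) - sse(oracle$par)), 1e-10)
})

test_that("inverse kinematics frames are order-independent without warm starts", {
  m <- fix_model()
  set.seed(6)
  n <- 5
  Q <- matrix(rep(c(0, 1.0, 0, 0.1, 0, 0, 0.1, 0.2, -0.3, -0.1, 0.25, -0.15),
                  each = n), n) + matrix(stats::rnorm(n * 12, 0, 0.02), n)
  rec <- make_marker_rec(m, Q)
  perm <- c(4, 1, 5, 3, 2)
  rec_p <- rec
  rec_p$pos <- rec$pos[perm, ]
  rec_p$mask <- rec$mask[perm, , drop = FALSE]
  ik <- inverse_kinematics(rec, m, warm_start = FALSE)
  ik_p <- inverse_kinematics(rec_p, m, warm_start = FALSE)
  expect_equal(ik_p$Q, ik$Q[perm, ], tolerance = 1e-10)
})

test_that("underdetermined frames raise an error naming the frame", {
  m <- fix_model()
  Q <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 1)
  rec <- make_marker_rec(m, Q)
  rec$mask[1, 3:14] <- FALSE  # two visible markers only
  expect_error(inverse_kinematics(rec, m), "frame 1")
})

test_that("dual-pass Butterworth is zero-phase with the configured response", {
  rate <- 175
  t <- seq(0, 2, by = 1 / rate)
  expect_equal(butterworth_dualpass(rep(3.2, 100), 15, rate), rep(3.2, 100),
               tolerance = 1e-6)
  lowf <- sin(2 * pi * 2 * t)
  filt <- butterworth_dualpass(lowf, 15, rate)
  xc <- stats::ccf(filt, lowf, lag.max = 10, plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)  # in phase: peak at lag zero
  highf <- sin(2 * pi * 60 * t)
  filt_h <- butterworth_dualpass(highf, 15, rate)
  core <- seq(50, length(t) - 50)
  expect_lt(max(abs(filt_h[core])) / max(abs(highf[core])), 0.1)
  expect_error(butterworth_dualpass(lowf, 100, rate), "Nyquist")
  # matrix input filters columns independently
  mat <- cbind(lowf, highf)
  fm <- butterworth_dualpass(mat, 15, rate)
  expect_equal(fm[, 1], filt, tolerance = 1e-12)
})

test_that("filtering commutes with differentiation on interior samples", {
  rate <- 175
  t <- seq(0, 2, by = 1 / rate)
  x <- sin(2 * pi * 3 * t) + 0.2 * sin(2 * pi * 40 * t)
  d_then_f <- butterworth_dualpass(ocmotion:::fd_diff(matrix(x), rate)[, 1], 10, rate)
  f_then_d <- ocmotion:::fd_diff(matrix(butterworth_dualpass(x, 10, rate)), rate)[, 1]
  # both operators are linear and time-invariant, so they commute away from
  # the record ends; the comparison stays beyond the filter's settling length
  core <- seq(120, length(t) - 120)
  expect_lt(max(abs(d_then_f[core] - f_then_d[core])), 1e-6 * max(abs(f_then_d)))
})

test_that("inverse dynamics is self-consistent and linear in external load", {
  # smooth noise-free trial: coordinates from clean markers, model-derived
  # GRFs; the pelvis residual is then only the finite-difference error
  trial <- generate_synthetic_trial(fix_model(), "straight", seed = 41,
                                    corruption = synthetic_corruption(
                                      marker_sd_mm = 0, sta_amp_mm = 0,
                                      grf_sd_n = 0))
  m <- trial$model_true
  Q <- trial$truth$X[, 1:12]
  grf <- downsample_grf(trial$plates, 175)
  id <- inverse_dynamics(m, Q, grf, 175)
  bw <- m$body_mass * 9.81
  rows <- ocmotion:::moi_rows(trial$moi)
  rms_resid <- sqrt(mean(id$residual_forces[rows, ]^2))
  expect_lt(rms_resid, 0.005 * bw)
  # +10 N vertical on plate 1 appears one-to-one in the vertical residual
  grf2 <- grf
  grf2$plates[[1]]$force[, 2] <- grf2$plates[[1]]$force[, 2] + 10
  id2 <- inverse_dynamics(m, Q, grf2, 175)
  expect_equal(mean(id$residual_forces[rows, 2] - id2$residual_forces[rows, 2]),
               10, tolerance = 1e-6)
  expect_error(inverse_dynamics(m, Q[1:10, ], grf, 175), "misaligned")
})
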
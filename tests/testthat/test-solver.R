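# Transcription derivatives and solver invariants on small instances.

test_that("collocation Jacobian matches a naive central difference", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  set.seed(1)
  N <- 4
  X <- trial$truth$X[1:N, ] + matrix(stats::rnorm(N * 32, 0, 0.01), N)
  U <- trial$truth$U[1:N, ] + matrix(stats::rnorm(N * 10, 0, 0.01), N)
  h <- trial$truth$h
  tr <- ocmotion:::cpp_traj_jacobian(m, X, U, h)
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v,
                            dims = c(tr$nrow, tr$ncol))
  lay <- list(N = N, nx = 32, nu = 10, nv = 42)
  fz <- function(z) {
    XU <- ocmotion:::z_to_XU(z, lay)
    ocmotion:::cpp_traj_residual(m, XU$X, XU$U, h)
  }
  Afd <- ocmotion:::fd_jac(fz, ocmotion:::XU_to_z(X, U), 1e-6)
  expect_lt(max(abs(A - Afd)) / max(abs(Afd)), 1e-5)
})

test_that("objective gradient matches finite differences and sums exactly", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  data <- make_tracking_data(trial, "marker")
  N <- 4
  data4 <- ocmotion:::truncate_tracking_data(data, N)
  lay <- ocmotion:::ocp_layout(m, N)
  w <- objective_weights("marker", "running")
  obj <- ocmotion:::make_ocp_objective(m, data4, w, (N - 1) / 175, lay)
  set.seed(2)
  X <- trial$truth$X[1:N, ] + matrix(stats::rnorm(N * 32, 0, 0.02), N)
  U <- pmax(trial$truth$U[1:N, ] + matrix(stats::rnorm(N * 10, 0, 0.02), N), 0)
  z <- ocmotion:::XU_to_z(X, U)
  o <- obj(z, TRUE)
  # reported objective equals the sum of its breakdown terms exactly
  expect_equal(o$J, sum(o$breakdown), tolerance = 1e-12)
  # breakdown terms match the exported cost functions
  traj <- msk_trajectory(m, X, U, (N - 1) / 175)
  expect_equal(o$breakdown[["tracking"]],
               tracking_cost(data4, ocmotion:::predicted_signals(m, X, c("grf", "marker")), w),
               tolerance = 1e-12)
  expect_equal(o$breakdown[["muscular_effort"]],
               muscular_effort_cost(U[, 1:4], m, w), tolerance = 1e-12)
  expect_equal(o$breakdown[["torque_effort"]],
               torque_effort_cost(U[, 5:10], w), tolerance = 1e-12)
  expect_equal(o$breakdown[["regularization"]],
               regularization_cost(traj, w), tolerance = 1e-12)
  idx <- seq(1, lay$nz, by = 17)
  gfd <- vapply(idx, function(i) {
    d <- 1e-6 * max(1, abs(z[i]))
    zp <- z; zp[i] <- z[i] + d
    zm <- z; zm[i] <- z[i] - d
    (obj(zp, FALSE)$J - obj(zm, FALSE)$J) / (2 * d)
  }, numeric(1))
  expect_lt(max(abs(o$grad[idx] - gfd)) / max(1, max(abs(gfd))), 1e-5)
})

test_that("the block-tridiagonal KKT solve agrees with the general sparse path", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  data <- make_tracking_data(trial, "marker")
  N <- 6
  data6 <- ocmotion:::truncate_tracking_data(data, N)
  lay <- ocmotion:::ocp_layout(m, N)
  w <- objective_weights("marker", "running")
  obj <- ocmotion:::make_ocp_objective(m, data6, w, (N - 1) / 175, lay)
  con <- ocmotion:::make_ocp_constraints(m, lay, 1 / 175)
  z <- ocmotion:::XU_to_z(trial$truth$X[1:N, ], trial$truth$U[1:N, ])
  o <- obj(z, TRUE); cn <- con(z, TRUE)
  nz <- lay$nz; mc <- length(cn$c)
  H <- o$hess + Matrix::Diagonal(nz, 1e-3)
  g <- o$grad / max(abs(o$grad))
  A <- cn$A / 100
  cc <- cn$c / 100
  lo <- rep(-10, nz); hi <- rep(10, nz)
  st <- ocmotion:::kkt_block_structure(N, lay$nv, 32)
  qb <- ocmotion:::solve_kkt_blocked(H, g, A, cc, lo, hi, 1e-4, st)
  qg <- ocmotion:::solve_kkt_general(H, g, A, cc, lo, hi, 1e-4)
  expect_lt(max(abs(qb$d - qg$d)) / max(abs(qg$d)), 1e-6)
  expect_lt(max(abs(qb$lam - qg$lam)) / max(1, max(abs(qg$lam))), 1e-6)
  # bound handling: a fixed (equal-bound) variable stays fixed
  lo2 <- lo; hi2 <- hi
  lo2[5] <- 0; hi2[5] <- 0
  qb2 <- ocmotion:::solve_kkt_blocked(H, g, A, cc, lo2, hi2, 1e-4, st)
  expect_equal(qb2$d[5], 0, tolerance = 1e-12)
})

test_that("tracking cost is insensitive to resampling density", {
  # the 1/(N N_j) normalization keeps the cost comparable when the same
  # continuous signals are sampled at twice the node count
  w <- objective_weights("marker", "running")
  w$W_tra <- c(marker = 1)
  t1 <- seq(0, 1, length.out = 41)
  t2 <- seq(0, 1, length.out = 81)
  yf <- function(t) cbind(sin(2 * pi * t), cos(2 * pi * t))
  yh <- function(t) yf(t) + 0.3 * cbind(sin(4 * pi * t), cos(6 * pi * t))
  d1 <- tracking_data(list(marker = list(y = yf(t1))), rate = 40)
  d2 <- tracking_data(list(marker = list(y = yf(t2))), rate = 80)
  J1 <- tracking_cost(d1, list(marker = yh(t1)), w)
  J2 <- tracking_cost(d2, list(marker = yh(t2)), w)
  expect_lt(abs(J1 - J2) / J1, 0.05)
})
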
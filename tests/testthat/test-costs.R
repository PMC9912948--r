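# Objective terms and the collocation constraint stack: hand-evaluated
# examples, default weights, degenerate inputs.

test_that("tracking cost matches hand evaluation and handles masks", {
  w <- objective_weights("marker", "running")
  w$W_tra <- c(marker = 1)
  data <- tracking_data(list(marker = list(y = matrix(c(1, 2), 2, 1))), rate = 175)
  expect_identical(tracking_cost(data, list(marker = matrix(c(1, 2), 2, 1)), w), 0)
  expect_equal(tracking_cost(data, list(marker = matrix(0, 2, 1)), w),
               (1 + 4) / (2 * 1), tolerance = 1e-14)
  # occluded entries contribute zero without changing the normalization
  data2 <- tracking_data(list(marker = list(
    y = matrix(c(1, 2), 2, 1), mask = matrix(c(TRUE, FALSE), 2, 1))), rate = 175)
  expect_equal(tracking_cost(data2, list(marker = matrix(0, 2, 1)), w),
               1 / (2 * 1), tolerance = 1e-14)
  # unit mismatch between weight convention and data is a configuration error
  data3 <- tracking_data(list(marker = list(y = matrix(0, 2, 1), unit = "m")),
                         rate = 175)
  w3 <- objective_weights("marker", "running")
  expect_error(tracking_cost(data3, list(marker = matrix(0, 2, 1)), w3),
               "unit mismatch")
})

test_that("default objective weights match their documented values", {
  wm <- objective_weights("marker", "running")
  expect_equal(wm$W_tra[["marker"]], 1e-2)
  expect_equal(wm$W_tra[["grf"]], 1e-3)
  expect_equal(wm$W_mus, 1)
  expect_equal(wm$W_tor, 1e-1)
  expect_equal(wm$W_reg, 1e-3)
  wc <- objective_weights("coordinate", "running")
  expect_equal(wc$W_tra[["translation"]], 1e-3)
  expect_equal(wc$W_tra[["angle"]], 1e-1)
  expect_equal(wc$W_tra[["grf"]], 1e-3)
  ws <- objective_weights("marker", "standing")
  expect_equal(ws$W_tra[["grf"]], 1e-2)
  expect_equal(ws$W_reg, 0)
})

test_that("muscular effort: hand value, volume normalization, domain error", {
  m <- fix_model()
  w <- objective_weights("marker", "running")
  expect_identical(muscular_effort_cost(matrix(0, 3, 4), m, w), 0)
  # one muscle, unit weight: W/(N*Nmus) * w_norm * ne^3 with all equal
  # volumes: 1/(1*4) * 4 * 0.25 * 0.5^3 = 0.125 / ... build the exact case
  m1 <- m
  m1$muscles <- lapply(m$muscles, function(f) if (is.list(f)) f[1] else f[1])
  ex <- matrix(0.5, 1, 1)
  expect_equal(muscular_effort_cost(ex, m1, w), 0.125, tolerance = 1e-14)
  # volume weights (2, 1, 1) normalize to (0.5, 0.25, 0.25)
  m3 <- m
  m3$muscles <- lapply(m$muscles, function(f) if (is.list(f)) f[1:3] else f[1:3])
  m3$muscles$w <- c(2, 1, 1)
  ex3 <- matrix(1, 1, 3)
  expect_equal(muscular_effort_cost(ex3, m3, w), 1 / 3 * 1, tolerance = 1e-14)
  expect_error(muscular_effort_cost(matrix(-0.1, 1, 4), m, w), "negative")
})

test_that("torque effort: hand value and quadratic homogeneity", {
  w <- objective_weights("marker", "running")
  expect_identical(torque_effort_cost(matrix(0, 3, 6), w), 0)
  expect_equal(torque_effort_cost(matrix(2, 1, 1), w), 0.1 * 4, tolerance = 1e-14)
  tq <- matrix(stats::rnorm(12), 2, 6)
  expect_equal(torque_effort_cost(2 * tq, w), 4 * torque_effort_cost(tq, w),
               tolerance = 1e-12)
})

test_that("regularization: hand value on a two-node trajectory", {
  m <- fix_model_nomus()
  w <- objective_weights("marker", "running")
  # constant trajectory -> zero
  X <- matrix(1, 2, n_states(m)); U <- matrix(0.3, 2, n_controls(m))
  traj <- msk_trajectory(m, X, U, T = 1)
  expect_identical(regularization_cost(traj, w), 0)
  # single state changing 0 -> 3 over T = 1: W * (N-1)/(T^2 (ns+nc)) * 9
  X2 <- X; X2[2, 1] <- X2[1, 1] + 3
  traj2 <- msk_trajectory(m, X2, U, T = 1)
  expect_equal(regularization_cost(traj2, w),
               w$W_reg * 1 / (1 * (n_states(m) + n_controls(m))) * 9,
               tolerance = 1e-14)
})

test_that("constraint stack has the documented row count and is zero on rollouts", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  traj <- trial$truth
  cc <- dynamics_constraints(traj, m)
  nf <- n_residual(m)
  expect_length(cc, (traj$N - 1) * nf + nf - 6)
  # the backward-Euler blocks vanish on a backward-Euler rollout
  expect_lt(max(abs(cc[seq_len((traj$N - 1) * nf)])), 1e-8)
  expect_error(dynamics_constraints(list(N = 1), m), "nodes")
})

test_that("backward-Euler discretization error on activation dynamics is O(h)", {
  # hold a step excitation and compare the implicit-Euler activation
  # trajectory at two rates against a tight ODE reference: halving h should
  # roughly halve the max error
  skip_if_not_installed("deSolve")
  m <- fix_model()
  q <- rep(0, 12); q[2] <- 2
  ne <- 0.9
  rate_fn <- function(a) -muscle_dynamics_residual(
    m, rep(a, 4), rep(0, 4), rep(1, 4), rep(0, 4), rep(ne, 4), q)$activation[1]
  ref <- deSolve::ode(y = c(a = 0.1), times = seq(0, 0.04, by = 0.04 / 128),
                      func = function(t, y, p) list(rate_fn(y[1])), parms = NULL,
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  be_traj <- function(nsteps) {
    h <- 0.04 / nsteps
    a <- 0.1
    out <- numeric(nsteps)
    for (k in seq_len(nsteps)) {
      g <- function(a1) (a1 - a) / h - rate_fn(a1)
      a <- stats::uniroot(g, c(0, 1), tol = 1e-14)$root
      out[k] <- a
    }
    out
  }
  err <- function(nsteps) {
    sol <- be_traj(nsteps)
    refv <- ref[match(round((1:nsteps) * 0.04 / nsteps, 10),
                      round(ref[, "time"], 10)), "a"]
    max(abs(sol - refv))
  }
  e1 <- err(32); e2 <- err(64)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.5)
})

test_that("context samples are prepended before the motion of interest", {
  y <- matrix(seq_len(50), 50, 1)
  data <- tracking_data(list(grf = list(y = y)), rate = 175, moi = c(21L, 41L))
  d10 <- prepend_context(data, 10)
  expect_equal(d10$N, 30)
  expect_equal(d10$types$grf$y[1, 1], 11)
  expect_equal(d10$moi, c(11L, 31L))
  d0 <- prepend_context(data, 0)
  expect_equal(d0$types$grf$y[1, 1], 21)
  data2 <- tracking_data(list(grf = list(y = y)), rate = 175, moi = c(5L, 41L))
  expect_error(prepend_context(data2, 10), "lead-in")
})
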
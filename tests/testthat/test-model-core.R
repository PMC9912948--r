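# Model core: kinematics, implicit dynamics, contact, muscles, passive
# moments. Oracles: hand-computed rotations, an explicit forward-dynamics
# solve via mass-matrix factorization, ODE integration, energy conservation.

test_that("forward kinematics: identity pose, translation equivariance, hand rotation", {
  m <- fix_model()
  q0 <- rep(0, 12); q0[2] <- 1.03
  fk <- forward_kinematics(m, q0)
  # marker local position maps through the plain vertical offset at zero pose
  expect_equal(unname(fk$markers["SACR", ]),
               c(-0.12, 1.03 + 0.05, 0), tolerance = 1e-12)
  # translating the pelvis translates every marker by exactly t
  t3 <- c(0.5, 0.2, -0.3)
  fk2 <- forward_kinematics(m, q0 + c(t3, rep(0, 9)))
  expect_equal(fk2$markers,
               fk$markers + matrix(t3, nrow(fk$markers), 3, byrow = TRUE),
               tolerance = 1e-12)
  # 90 deg rotation of the right hip about the vertical axis: the marker's
  # local (x, z) offset relative to the hip maps through the hand-written
  # rotation matrix [x; z] -> [z; -x] ... for Ry(90): x' = z, z' = -x
  q90 <- q0; q90[7] <- pi / 2
  fk90 <- forward_kinematics(m, q90)
  hip <- c(0, q0[2] - 0.10, 0.12)
  # marker local offset from the hip: shank-local position plus the thigh
  # translation; Ry(90) maps (x, y, z) -> (z, y, -x)
  loc <- m$markers$local[which(m$markers$name == "RTOE"), ] + c(0, -0.45, 0)
  expected <- hip + c(loc[3], loc[2], -loc[1])
  expect_equal(unname(fk90$markers["RTOE", ]), unname(expected), tolerance = 1e-12)
  expect_error(forward_kinematics(m, rep(0, 5)), "length")
})

test_that("implicit dynamics residual is zero at rest without gravity and at standing", {
  m <- fix_model()
  m$gravity <- c(0, 0, 0)
  m$passive$k[] <- 0; m$passive$d[] <- 0
  q <- rep(0, 12); q[2] <- 2  # well above ground, no contact
  lmt <- muscle_geometry(m, q)$lmt
  # algebraically consistent muscle state at zero activation: tendon force
  # equals the passive fiber force
  s <- vapply(1:4, function(i) stats::uniroot(function(si)
    muscle_dynamics_residual(m, rep(0, 4), rep(0, 4),
                             replace(rep(1, 4), i, si), rep(0, 4),
                             rep(0, 4), q)$contraction[i],
    c(0.4, 1.6), tol = 1e-14)$root, numeric(1))
  x <- c(q, rep(0, 12), rep(0, 4), s)
  r <- implicit_dynamics_residual(m, x, rep(0, 32), rep(0, 10))
  expect_lt(max(abs(r)), 1e-5)  # smoothing tail of the contact law remains
  # standing equilibrium under gravity: f(x, 0, u) = 0
  eq <- fix_standing()
  expect_lt(max(abs(eq$residual)), 1e-8)
})

test_that("residual vanishes for xdot from an explicit forward-dynamics solve", {
  st <- fix_random_state()
  m <- st$model
  nd <- 12; nm <- 4
  # mass matrix by columns of the inverse-dynamics map (factorization oracle)
  rnea0 <- ocmotion:::cpp_rnea(m, st$q, st$qd, rep(0, nd), TRUE)
  M <- vapply(seq_len(nd), function(j) {
    e <- rep(0, nd); e[j] <- 1
    ocmotion:::cpp_rnea(m, st$q, st$qd, e, TRUE) - rnea0
  }, numeric(nd))
  expect_lt(max(abs(M - t(M))), 1e-9)  # mass matrix symmetric
  sdot <- vapply(seq_len(nm), function(i) stats::uniroot(function(v)
    muscle_dynamics_residual(m, st$a, rep(0, nm), st$s,
                             replace(rep(0, nm), i, v), st$u[1:4], st$q)$contraction[i],
    c(-2000, 2000), tol = 1e-14)$root, numeric(1))
  tau <- ocmotion:::cpp_applied_tau(m, st$x, sdot, st$u)
  qdd <- solve(M, tau - rnea0)
  adot <- -muscle_dynamics_residual(m, st$a, rep(0, nm), st$s, sdot,
                                    st$u[1:4], st$q)$activation
  xdot <- c(st$qd, qdd, adot, sdot)
  r <- implicit_dynamics_residual(m, st$x, xdot, st$u)
  expect_lt(max(abs(r)), 1e-7)
})

test_that("ground contact: smooth tail, monotonicity, static force balance", {
  m <- fix_model()
  q <- rep(0, 12); q[2] <- 1.09  # all points >= 5 cm above ground
  gc <- ground_contact_forces(m, q, rep(0, 12))
  expect_true(all(gc$points[, 2] >= 0.05))
  expect_true(all(abs(gc$forces[, 2]) < 1e-3))
  # vertical force monotone non-decreasing in penetration at zero velocity
  heights <- seq(1.06, 0.99, by = -0.005)
  fy <- vapply(heights, function(h) {
    qq <- q; qq[2] <- h
    sum(ground_contact_forces(m, qq, rep(0, 12))$forces[, 2])
  }, numeric(1))
  expect_true(all(diff(fy) >= 0))
  # solved static standing supports exactly body weight
  eq <- fix_standing()
  m2 <- fix_model_offset()
  gc2 <- ground_contact_forces(m2, eq$x[1:12], rep(0, 12))
  expect_equal(sum(gc2$forces[, 2]), m2$body_mass * 9.81, tolerance = 1e-3)
  # C1: the finite-difference derivative of the vertical force w.r.t. pelvis
  # height is continuous across the contact boundary
  dF <- function(h) {
    d <- 1e-8
    qa <- q; qa[2] <- h + d; qb <- q; qb[2] <- h - d
    (sum(ground_contact_forces(m, qa, rep(0, 12))$forces[, 2]) -
       sum(ground_contact_forces(m, qb, rep(0, 12))$forces[, 2])) / (2 * d)
  }
  # continuously differentiable across the contact boundary: the one-sided
  # derivative gap shrinks proportionally with the probe distance
  h0 <- 1.03  # points exactly at the ground
  jump <- function(del) abs(dF(h0 + del) - dF(h0 - del))
  expect_lt(jump(1e-6), 0.4 * jump(1e-5))
})

test_that("moment arms equal the negative muscle-tendon length derivative", {
  m <- fix_model()
  q <- fix_random_state()$q
  mg <- muscle_geometry(m, q)
  d <- 1e-6
  for (dof in c(8, 11)) {
    qp <- q; qp[dof] <- q[dof] + d
    qm <- q; qm[dof] <- q[dof] - d
    dl <- (muscle_geometry(m, qp)$lmt - muscle_geometry(m, qm)$lmt) / (2 * d)
    expect_equal(mg$moment_arm[, dof], -dl, tolerance = 1e-6)
  }
})

test_that("passive moments: quiet mid-range, restoring beyond an 8-degree limit, odd", {
  m <- fix_model()
  q <- rep(0, 12); qd <- rep(0, 12)
  q[8] <- 0.3  # mid-range hip flexion
  expect_lt(abs(passive_joint_moment(m, q, qd)[8]), 0.01)
  # configure a toe-joint-like limit: stiffening beyond 8 deg plantarflexion
  m2 <- m
  m2$passive$qhi[9] <- 8 * pi / 180
  m2$passive$qlo[9] <- -60 * pi / 180
  q2 <- rep(0, 12); q2[9] <- 20 * pi / 180  # 12 deg beyond the limit
  mom <- passive_joint_moment(m2, q2, qd)[9]
  expect_lt(mom, 0)            # restoring (dorsiflexing) moment
  expect_gt(abs(mom), 0.5)     # clearly active
  # odd symmetry for symmetric limits
  m3 <- m
  m3$passive$qlo[7] <- -0.5; m3$passive$qhi[7] <- 0.5
  qa <- rep(0, 12); qa[7] <- 0.4
  qb <- rep(0, 12); qb[7] <- -0.4
  expect_equal(passive_joint_moment(m3, qa, qd)[7],
               -passive_joint_moment(m3, qb, qd)[7], tolerance = 1e-12)
})

test_that("muscle dynamics: excitation equilibrium, ODE oracle, isometric balance", {
  m <- fix_model()
  q <- rep(0, 12); q[2] <- 2
  # n_e = a, adot = 0 -> activation residual zero
  r <- muscle_dynamics_residual(m, rep(0.4, 4), rep(0, 4), rep(1, 4),
                                rep(0, 4), rep(0.4, 4), q)
  expect_equal(max(abs(r$activation)), 0, tolerance = 1e-14)
  # step excitation: implicit-Euler trajectory vs an explicit ODE oracle
  skip_if_not_installed("deSolve")
  ne <- 1
  rate_fn <- function(a) -muscle_dynamics_residual(
    m, rep(a, 4), rep(0, 4), rep(1, 4), rep(0, 4), rep(ne, 4), q)$activation[1]
  sol <- deSolve::ode(y = c(a = 0), times = seq(0, 0.05, by = 1e-4),
                      func = function(t, y, p) list(rate_fn(y[1])), parms = NULL,
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  # implicit Euler on the same residual at two steps; the O(h) error is
  # removed by Richardson extrapolation before the 1e-6 comparison
  be_end <- function(h) {
    a <- 0
    for (k in seq_len(round(0.05 / h))) {
      g <- function(a1) (a1 - a) / h - rate_fn(a1)
      a <- stats::uniroot(g, c(a - 1e-3, 1), tol = 1e-14)$root
    }
    a
  }
  a1 <- be_end(2e-5); a2 <- be_end(1e-5)
  expect_equal(2 * a2 - a1, unname(sol[nrow(sol), "a"]), tolerance = 1e-6)
  # isometric Hill balance: residual zero when the tendon force matches the
  # hand-evaluated active + passive fiber force
  s0 <- 1.02
  lmt <- muscle_geometry(m, q)$lmt[1]
  a0 <- 0.6
  fL <- exp(-((s0 - 1) / 0.45)^2)
  fPE <- 2 * (0.5 * ((s0 - 1) + sqrt((s0 - 1)^2 + 0.05^2)))^2
  kt <- m$muscles$kt[1]
  lt_tilde <- (lmt - s0 * m$muscles$lmopt[1]) / m$muscles$ltslack[1]
  zz <- 0.5 * ((lt_tilde - 1) + sqrt((lt_tilde - 1)^2 + 0.01^2))
  fT <- 0.2 * (exp(kt * zz) - 1)
  r2 <- muscle_dynamics_residual(m, rep(a0, 4), rep(0, 4), rep(s0, 4),
                                 rep(0, 4), rep(a0, 4), q)$contraction[1]
  expect_equal(r2, fT - (a0 * fL + fPE), tolerance = 1e-12)
})

test_that("root-segment markers ignore internal joint changes", {
  m <- fix_model()
  q <- rep(0, 12); q[2] <- 1.03
  fk1 <- forward_kinematics(m, q)
  q2 <- q; q2[7:12] <- c(0.3, -0.5, 0.7, -0.2, 0.4, -0.9)
  fk2 <- forward_kinematics(m, q2)
  root <- which(m$markers$dof <= 6)
  expect_equal(fk1$markers[root, ], fk2$markers[root, ], tolerance = 1e-14)
})

test_that("airborne passive dynamics conserve mechanical energy (ODE oracle)", {
  skip_if_not_installed("deSolve")
  m <- fix_model_nomus()
  nd <- 12
  q0 <- rep(0, nd); q0[2] <- 3  # flight: no contact throughout
  qd0 <- c(0.3, 0.5, -0.2, 1.0, 0.8, -0.6, 0.5, -0.4, 0.3, -0.5, 0.4, -0.3)
  m$passive$k[] <- 0; m$passive$d[] <- 0  # conservative rigid-body motion
  deriv <- function(t, y, p) {
    q <- y[1:nd]; qd <- y[nd + 1:nd]
    rnea0 <- ocmotion:::cpp_rnea(m, q, qd, rep(0, nd), FALSE)
    M <- vapply(seq_len(nd), function(j) {
      e <- rep(0, nd); e[j] <- 1
      ocmotion:::cpp_rnea(m, q, qd, e, FALSE) - rnea0
    }, numeric(nd))
    list(c(qd, solve(M, -rnea0)))
  }
  energy <- function(q, qd) {
    rnea0 <- ocmotion:::cpp_rnea(m, q, qd, rep(0, nd), FALSE)
    M <- vapply(seq_len(nd), function(j) {
      e <- rep(0, nd); e[j] <- 1
      ocmotion:::cpp_rnea(m, q, qd, e, FALSE) - rnea0
    }, numeric(nd))
    fk <- forward_kinematics(m, q)
    com_y <- 0
    for (b in seq_along(m$body$mass)) {
      d <- m$body$dof[b]
      p <- fk$origins[d, ] + fk$rotations[, , d] %*% m$body$com[b, ]
      com_y <- com_y + m$body$mass[b] * p[2]
    }
    0.5 * sum(qd * (M %*% qd)) + 9.81 * com_y
  }
  sol <- deSolve::ode(y = c(q0, qd0), times = seq(0, 0.2, by = 0.01),
                      func = deriv, parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  e0 <- energy(q0, qd0)
  e1 <- energy(sol[nrow(sol), 2:13], sol[nrow(sol), 14:25])
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("model validation reports all violations", {
  m <- fix_model()
  m$body$mass[1] <- -1
  m$markers$dof[1] <- 99L
  err <- tryCatch(validate_model(m), error = function(e) conditionMessage(e))
  expect_match(err, "masses")
  expect_match(err, "marker")
})

test_that("model YAML config round-trips", {
  m <- fix_model()
  path <- tempfile(fileext = ".yml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$dof$axis, m$dof$axis, tolerance = 1e-12)
  expect_equal(m2$muscles$poly, m$muscles$poly, tolerance = 1e-12)
  expect_equal(m2$contacts$k, m$contacts$k)
  expect_equal(m2$tor_gain, m$tor_gain)
  q <- fix_random_state()$q
  expect_equal(forward_kinematics(m2, q)$markers,
               forward_kinematics(m, q)$markers, tolerance = 1e-12)
  unlink(path)
})
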
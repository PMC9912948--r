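# Static standing calibration: offset recovery, equilibrium, restart
# selection. One multi-restart solve is shared across the assertions.

test_that("standing calibration recovers pose and sole offset from an N-pose", {
  trial <- fix_trial_clean()
  sdata <- make_static_tracking_data(trial, "marker")
  st <- solve_standing(trial$model, sdata, settings = solver_settings(seed = 7))
  # injected 12 mm offset recovered within 0.5 mm
  expect_equal(1000 * st$offset, 12, tolerance = 0.5)
  # generating pose recovered within 1e-3 rad per DoF
  expect_lt(max(abs(st$x[1:12] - trial$static$x[1:12])), 1e-3)
  # static equilibrium f(x, 0, u) = 0 within the solver tolerance
  m2 <- st$model
  r <- implicit_dynamics_residual(m2, st$x, rep(0, length(st$x)), st$u)
  expect_lte(max(abs(r)), 1e-3)
  expect_lte(st$max_violation, 1e-3)
  # default restart count and minimum-objective selection (first on ties)
  expect_equal(st$restarts$n, 10)
  expect_equal(st$restarts$selected, which.min(st$restarts$objective))
  expect_true(st$convergence$status == "converged")
  fix_env$standing_fit <- st  # reused by the acceptance checks
})

test_that("standing fails loudly when every restart fails", {
  trial <- fix_trial_clean()
  sdata <- make_static_tracking_data(trial, "marker")
  # make the problem unsolvable: demand an absurd feasibility tolerance
  broken <- solver_settings(tol = 1e-14, constraint_tol = 1e-14, restarts = 2,
                            max_iterations = 3, seed = 1)
  expect_error(solve_standing(trial$model, sdata, settings = broken),
               "all restarts")
})
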
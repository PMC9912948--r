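# RMSD, unit scalings, residual metrics and convergence reporting.

test_that("rmsd matches hand values and validates shapes", {
  expect_identical(unname(rmsd(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(unname(rmsd(c(0, 0), c(3, 4))), sqrt(12.5), tolerance = 1e-14)
  expect_error(rmsd(1:3, 1:4), "mismatch")
  # symmetric and invariant to a common shift of both series
  set.seed(2)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_equal(rmsd(a + 5, b + 5), rmsd(a, b), tolerance = 1e-12)
})

test_that("aggregation uses the sample standard deviation", {
  agg <- aggregate_rmsd(c(1, 2, 3))
  expect_equal(agg[["mean"]], 2)
  expect_equal(agg[["sd"]], 1)
  expect_equal(agg[["n"]], 3)
})

test_that("unit scalings match their definitions and are linear", {
  expect_equal(scale_units(70 * 9.81, "grf", body_mass = 70), 100,
               tolerance = 1e-12)
  expect_equal(scale_units(123.6, "moment", body_mass = 70, body_height = 1.8),
               100 * 123.6 / (70 * 9.81 * 1.8), tolerance = 1e-12)
  expect_equal(scale_units(123.6, "moment", body_mass = 70, body_height = 1.8),
               10.0, tolerance = 1e-2)
  expect_equal(scale_units(850, "residual_force", body_mass = 70, grf_max = 850),
               100, tolerance = 1e-12)
  expect_equal(scale_units(10, "residual_moment", body_mass = 70,
                           body_height = 2, grf_max = 500),
               100 * 10 / (500 * 2), tolerance = 1e-12)
  a <- 3.7
  expect_equal(scale_units(a * 50, "grf", body_mass = 70),
               a * scale_units(50, "grf", body_mass = 70), tolerance = 1e-12)
  expect_error(scale_units(1, "grf", body_mass = -1), "positive")
  expect_error(scale_units(1, "residual_force", body_mass = 70), "positive")
})

test_that("net GRF maximum uses the two-feet vector sum", {
  grf <- rbind(c(100, 600, 0, 50, 300, 0),
               c(0, 800, 0, 0, 100, 0))
  expect_equal(grf_max_net(grf),
               max(sqrt(150^2 + 900^2), sqrt(0 + 900^2)), tolerance = 1e-12)
})

test_that("inverse-dynamics residual metrics scale to GRFmax conventions", {
  id <- structure(list(residual_forces = matrix(30, 4, 3),
                       residual_moments = matrix(6, 4, 3),
                       rate = 175), class = "msk_id")
  m <- fix_model()
  rm <- residual_metrics(id, m, grf_max = 1000)
  expect_equal(rm$pelvis_force_n, 30, tolerance = 1e-12)
  expect_equal(rm$pelvis_force_grfmax_pct, 3, tolerance = 1e-12)
  expect_equal(rm$pelvis_moment_grfmax_bh_pct, 100 * 6 / (1000 * m$body_height),
               tolerance = 1e-12)
})

test_that("convergence reports parse logs and compute per-iteration cost", {
  rep <- convergence_report(c("iterations: 100", "cpu_time_s: 50",
                              "nlp_cpu_s: 5", "scaled_nlp_error: 9e-5"))
  expect_equal(rep$cpu_per_iteration_s, 0.5)
  expect_equal(rep$nlp_eval_share_pct, 10)
  expect_equal(rep$scaled_nlp_error, 9e-5)
  expect_error(convergence_report("no separator here"), "unparseable")
  expect_error(convergence_report("key: not_a_number"), "unparseable")
})
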
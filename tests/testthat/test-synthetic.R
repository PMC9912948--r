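# Synthetic trial generator: determinism, dynamic consistency, heading,
# corruption statistics.

test_that("generated trajectories satisfy the implicit dynamics with FD xdot", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  traj <- trial$truth
  worst <- 0
  for (k in seq(2, traj$N)) {
    xd <- (traj$X[k, ] - traj$X[k - 1, ]) / traj$h
    r <- implicit_dynamics_residual(m, traj$X[k, ], xd, traj$U[k, ])
    worst <- max(worst, max(abs(r)))
  }
  expect_lt(worst, 1e-6)
})

test_that("generation is bit-reproducible from the seed", {
  m <- fix_model_offset()
  t1 <- generate_reference_motion(m, "curved", seed = 9, N = 30)
  t2 <- generate_reference_motion(m, "curved", seed = 9, N = 30)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$U, t2$U)
  t3 <- generate_reference_motion(m, "curved", seed = 10, N = 30)
  expect_false(identical(t1$U, t3$U))
})

test_that("the direction-change task turns the pelvis by at least 60 degrees", {
  trial <- fix_trial_clean()
  heading <- abs(trial$truth$X[trial$truth$N, 4] - trial$truth$X[1, 4]) * 180 / pi
  expect_gte(heading, 60)
})

test_that("zero corruption reproduces the clean markers exactly", {
  trial <- fix_trial_clean()
  expect_identical(trial$markers$pos, trial$markers_clean$pos)
})

test_that("marker noise has the configured standard deviation", {
  m <- fix_model_offset()
  truth <- generate_reference_motion(m, "straight", seed = 3, N = 70)
  meas <- synthesize_measurements(truth, m,
                                  synthetic_corruption(marker_sd_mm = 2,
                                                       sta_amp_mm = 0,
                                                       grf_sd_n = 0), seed = 4)
  noise <- meas$markers$pos - meas$markers_clean$pos
  expect_equal(stats::sd(as.vector(noise)), 2, tolerance = 0.05)
})

test_that("the soft-tissue artifact is a narrow-band low-frequency offset", {
  m <- fix_model_offset()
  truth <- generate_reference_motion(m, "straight", seed = 3, N = 70)
  meas <- synthesize_measurements(truth, m,
                                  synthetic_corruption(marker_sd_mm = 0,
                                                       sta_amp_mm = 5,
                                                       sta_freq_hz = 1.5,
                                                       grf_sd_n = 0), seed = 4)
  art <- meas$markers$pos - meas$markers_clean$pos
  # leg markers carry the artifact, pelvis markers do not
  leg_cols <- which(rep(m$markers$dof, each = 3) > 6)
  expect_gt(max(abs(art[, leg_cols])), 2)
  expect_equal(max(abs(art[, -leg_cols])), 0)
  # the offset is a pure sinusoid at the configured frequency: a harmonic
  # regression at 1.5 Hz explains it (almost) exactly, a detuned one does not
  sig <- art[, leg_cols[1]]
  t <- (seq_along(sig) - 1) / 175
  fit_r2 <- function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    # the fit is perfect by construction, which lm's summary warns about
    suppressWarnings(summary(stats::lm(sig ~ X))$r.squared)
  }
  expect_gt(fit_r2(1.5), 0.999999)
  expect_lt(fit_r2(3.5), 0.9)
  expect_error(synthetic_corruption(marker_sd_mm = -1), "non-negative")
})

test_that("force-plate recordings are consistent with the truth contact model", {
  trial <- fix_trial_clean()
  m <- trial$model_true
  grf_nodes <- ocmotion:::cpp_grf_traj(m, trial$truth$X)
  # decimated plate samples coincide with the node-state contact forces
  ds <- downsample_grf(trial$plates, 175)
  expect_equal(ds$plates[[1]]$force[1:trial$truth$N, ], grf_nodes[, 1:3],
               tolerance = 1e-9)
  expect_equal(ds$plates[[2]]$force[1:trial$truth$N, ], grf_nodes[, 4:6],
               tolerance = 1e-9)
})

test_that("trial fixtures write and read back as TRC/STO", {
  trial <- fix_trial_clean()
  dir <- tempfile()
  dir.create(dir)
  write_trc(trial$markers, file.path(dir, "markers.trc"))
  write_grf_sto(trial$plates, file.path(dir, "grf.sto"))
  mk <- read_trc(file.path(dir, "markers.trc"))
  expect_equal(mk$pos, unname(trial$markers$pos), tolerance = 1e-5)
  gr <- read_grf_sto(file.path(dir, "grf.sto"))
  expect_equal(gr$plates[[1]]$force, unname(trial$plates$plates[[1]]$force),
               tolerance = 1e-8)
  unlink(dir, recursive = TRUE)
})
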
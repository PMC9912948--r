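# Shared fixtures: models and trials are built once per test run and reused.
# Everything is generated in code; no binary data.

fix_env <- new.env()

fix_model <- function() {
  if (is.null(fix_env$model)) fix_env$model <- toy_model()
  fix_env$model
}

fix_model_nomus <- function() {
  if (is.null(fix_env$model0)) fix_env$model0 <- toy_model(n_mus = 0)
  fix_env$model0
}

# model with the true sole offset applied (as the generator uses it)
fix_model_offset <- function() {
  m <- fix_model()
  m$contacts$offset <- 0.012
  m
}

fix_standing <- function() {
  if (is.null(fix_env$standing))
    fix_env$standing <- find_standing_state(fix_model_offset())
  fix_env$standing
}

# clean (noise-free) direction-change trial
fix_trial_clean <- function() {
  if (is.null(fix_env$trial_clean))
    fix_env$trial_clean <- generate_synthetic_trial(
      fix_model(), "direction_change", seed = 1,
      corruption = synthetic_corruption(marker_sd_mm = 0, sta_amp_mm = 0,
                                        grf_sd_n = 0))
  fix_env$trial_clean
}

# noisy trial at the study-like corruption defaults
fix_trial_noisy <- function() {
  if (is.null(fix_env$trial_noisy))
    fix_env$trial_noisy <- generate_synthetic_trial(fix_model(),
                                                    "direction_change", seed = 2)
  fix_env$trial_noisy
}

# a state/control pair with physiologically sensible muscle states
fix_random_state <- function(seed = 42) {
  m <- fix_model()
  set.seed(seed)
  q <- c(0.1, 1.0, -0.05, 0.3, 0.05, -0.1, 0.2, 0.3, -0.4, -0.1, 0.2, -0.3)
  qd <- stats::rnorm(12, 0, 1)
  a <- stats::runif(4, 0.1, 0.8)
  lmt <- muscle_geometry(m, q)$lmt
  s <- (lmt - m$muscles$ltslack) / m$muscles$lmopt + stats::runif(4, -0.03, 0.03)
  u <- c(stats::runif(4, 0, 1), stats::rnorm(6, 0, 0.2))
  list(model = m, q = q, qd = qd, a = a, s = s, x = c(q, qd, a, s), u = u)
}
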
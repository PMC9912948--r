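# End-to-end orchestration of the three reconstruction routes (marker
# tracking, coordinate tracking, inverse methods) and the comparison report.

#' Run configuration
#'
#' @param modes subset of `"marker"`, `"coordinate"`, `"inverse"`.
#' @param settings a [solver_settings()].
#' @param weights named list of [objective_weights()] overrides per mode
#'   (optional).
#' @param filter_cutoff_hz low-pass cutoff for the inverse-dynamics pathway.
#' @param n_pre context samples prepended before the motion of interest.
#' @param out_dir optional directory for on-disk artifacts (STO trajectories
#'   and a JSON run report).
#' @return object of class `run_config`.
#' @export
run_config <- function(modes = c("marker", "coordinate", "inverse"),
                       settings = solver_settings(), weights = list(),
                       filter_cutoff_hz = 15, n_pre = 10, out_dir = NULL) {
  modes <- match.arg(modes, c("marker", "coordinate", "inverse"),
                     several.ok = TRUE)
  structure(list(modes = modes, settings = settings, weights = weights,
                 filter_cutoff_hz = filter_cutoff_hz, n_pre = n_pre,
                 out_dir = out_dir), class = "run_config")
}

#' Run the full reconstruction pipeline on one trial
#'
#' Executes, per requested mode: standing calibration (tracking the static
#' N-pose frame), then marker-tracking reconstruction from the raw markers,
#' coordinate-tracking reconstruction from inverse-kinematics output, and/or
#' the inverse pipeline (IK, dual-pass filtering, inverse dynamics). Metrics
#' are evaluated over the motion of interest only. A failing mode is
#' recorded and the remaining modes still run.
#'
#' @param trial a [generate_synthetic_trial()] result (or an object with the
#'   same structure built from measured recordings).
#' @param config a [run_config()].
#' @return object of class `trial_report` with per-mode results and metrics.
#' @export
run_trial <- function(trial, config = run_config()) {
  model <- trial$model
  bw <- model$body_mass * 9.81
  out <- list(task = trial$manifest$task, seed = trial$manifest$seed,
              modes = list(), errors = list())
  ik <- NULL
  need_ik <- any(c("coordinate", "inverse") %in% config$modes)
  if (need_ik) {
    ik <- tryCatch(inverse_kinematics(trial$markers, model),
                   error = function(e) {
                     out$errors$ik <<- conditionMessage(e); NULL
                   })
  }
  grf_ref <- downsample_grf(trial$plates, trial$markers$rate)
  truth_grf <- cpp_grf_traj(model_for_cpp(trial$model_true), trial$truth$X)
  moi <- trial$moi
  rows <- moi_rows(moi)
  grf_max <- grf_max_net(cbind(grf_ref$plates[[1]]$force[rows, , drop = FALSE],
                               grf_ref$plates[[2]]$force[rows, , drop = FALSE]))
  for (mode in intersect(config$modes, c("marker", "coordinate"))) {
    res <- tryCatch({
      if (mode == "coordinate" && is.null(ik)) stop("inverse kinematics failed")
      sdata <- make_static_tracking_data(trial, mode)
      st <- solve_standing(model, sdata, mode = mode,
                           weights = config$weights[[paste0(mode, "_standing")]],
                           settings = config$settings)
      data <- make_tracking_data(trial, mode, ik = ik)
      data <- prepend_context_full(data, trial, config$n_pre)
      rec <- solve_reconstruction(st$model, data, mode,
                                  weights = config$weights[[mode]],
                                  settings = config$settings,
                                  initial_guess = st)
      list(standing = st, recon = rec,
           metrics = evaluate_reconstruction(rec, trial, ik, grf_max))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) out$errors[[mode]] <- res else out$modes[[mode]] <- res
  }
  if ("inverse" %in% config$modes) {
    res <- tryCatch({
      if (is.null(ik)) stop("inverse kinematics failed")
      qf <- butterworth_dualpass(ik$Q, config$filter_cutoff_hz, ik$rate)
      grf_f <- downsample_grf(trial$plates, trial$markers$rate)
      grf_f$plates <- lapply(grf_f$plates, function(pl) {
        pl$force <- butterworth_dualpass(pl$force, config$filter_cutoff_hz, ik$rate)
        pl
      })
      id <- inverse_dynamics(model, qf, grf_f, ik$rate,
                             filter_settings = list(order = 3,
                                                    cutoff_hz = config$filter_cutoff_hz,
                                                    dual_pass = TRUE))
      mk_mod <- t(vapply(seq_len(nrow(ik$Q)), function(k)
        as.vector(t(cpp_markers(model_for_cpp(model), ik$Q[k, ]))) * 1000,
        numeric(3 * length(model$markers$dof))))
      list(ik = ik, id = id,
           metrics = list(
             marker_rmsd_mm = aggregate_rmsd(rmsd(mk_mod[rows, , drop = FALSE],
                                                  trial$markers$pos[rows, , drop = FALSE])),
             residuals = residual_metrics(id, model, grf_max, moi)))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) out$errors$inverse <- res else out$modes$inverse <- res
  }
  class(out) <- "trial_report"
  if (!is.null(config$out_dir)) write_trial_artifacts(out, trial, config$out_dir)
  out
}

# tracking data spanning moi plus n_pre lead-in (trial recordings span the
# full generated range already)
prepend_context_full <- function(data, trial, n_pre) {
  prepend_context(data, n_pre)
}

#' Reconstruction metrics against measured data, inverse methods and truth
#'
#' Marker positions and GRFs are compared against the measured (corrupted)
#' data; translations and angles against inverse kinematics when available;
#' joint angles and GRFs additionally against the known synthetic truth.
#' RMSDs are aggregated as mean +/- sd over the signals of each type, over
#' the motion of interest.
#'
#' @param rec an `msk_recon`.
#' @param trial the source [generate_synthetic_trial()] object.
#' @param ik an `msk_ik` fit or NULL.
#' @param grf_max maximal net GRF (N) over the motion of interest.
#' @return named list of metric aggregates.
#' @export
evaluate_reconstruction <- function(rec, trial, ik = NULL, grf_max = NULL) {
  model <- rec$model
  bw <- model$body_mass * 9.81
  nd <- n_dof(model)
  # the reconstruction spans [moi_start - n_pre, moi_end); map its motion of
  # interest onto the full-recording frame indices
  rows_rec <- moi_rows(rec$data$moi)
  offset_full <- trial$moi[1] - rec$data$moi[1]
  rows_full <- rows_rec + offset_full
  X <- rec$trajectory$X
  mk_hat <- 1000 * cpp_predicted(model_for_cpp(model), X, FALSE)$markers
  grf_hat <- (100 / bw) * cpp_grf_traj(model_for_cpp(model), X)
  grf_ds <- downsample_grf(trial$plates, trial$markers$rate)
  grf_meas <- (100 / bw) * cbind(grf_ds$plates[[1]]$force, grf_ds$plates[[2]]$force)
  out <- list(
    marker_rmsd_mm = aggregate_rmsd(rmsd(mk_hat[rows_rec, , drop = FALSE],
                                         trial$markers$pos[rows_full, , drop = FALSE])),
    grf_rmsd_bw_pct = aggregate_rmsd(rmsd(grf_hat[rows_rec, , drop = FALSE],
                                          grf_meas[rows_full, , drop = FALSE])))
  if (!is.null(ik)) {
    out$translation_rmsd_mm <- aggregate_rmsd(
      rmsd(1000 * X[rows_rec, 1:3, drop = FALSE],
           1000 * ik$Q[rows_full, 1:3, drop = FALSE]))
    out$angle_rmsd_deg <- aggregate_rmsd(
      rmsd((180 / pi) * X[rows_rec, 4:nd, drop = FALSE],
           (180 / pi) * ik$Q[rows_full, 4:nd, drop = FALSE]))
  }
  if (!is.null(trial$truth)) {
    truth_grf <- (100 / bw) * cpp_grf_traj(model_for_cpp(trial$model_true),
                                           trial$truth$X)
    out$angle_rms_vs_truth_deg <- sqrt(mean(
      ((180 / pi) * (X[rows_rec, 4:nd] - trial$truth$X[rows_full, 4:nd]))^2))
    out$grf_rms_vs_truth_bw_pct <- sqrt(mean(
      (grf_hat[rows_rec, ] - truth_grf[rows_full, ])^2))
  }
  if (!is.null(grf_max))
    out$residuals <- residual_metrics(rec, model, grf_max)
  out$convergence <- convergence_report(rec)
  out
}

write_trial_artifacts <- function(report, trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf("%s_seed%d", report$task, report$seed)
  for (mode in intersect(names(report$modes), c("marker", "coordinate"))) {
    rec <- report$modes[[mode]]$recon
    df <- data.frame(time = rec$trajectory$times)
    Q <- rec$trajectory$X[, seq_len(n_dof(rec$model)), drop = FALSE]
    Q[, 4:ncol(Q)] <- Q[, 4:ncol(Q)] * 180 / pi
    colnames(Q) <- rec$model$dof$name
    write_sto(cbind(df, Q),
              file.path(dir, sprintf("%s_%s_coordinates.sto", tag, mode)),
              metadata = list(inDegrees = "yes"))
  }
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(dir, sprintf("%s_report.json", tag)))
  invisible(dir)
}

report_to_list <- function(report) {
  lapply(report$modes, function(mo) {
    if (!is.null(mo$metrics)) mo$metrics else NULL
  })
}

#' Run and aggregate a batch of trials
#'
#' Runs [run_trial()] on every trial and aggregates the per-mode marker and
#' GRF RMSDs as mean +/- sd per motion type. Failed trials are recorded and
#' excluded from the aggregates.
#'
#' @param trials list of trials.
#' @param config a [run_config()].
#' @return object of class `batch_report`.
#' @export
run_batch <- function(trials, config = run_config()) {
  if (length(trials) == 0) stop("empty trial list")
  reports <- lapply(trials, function(tr)
    tryCatch(run_trial(tr, config), error = function(e) conditionMessage(e)))
  failed <- vapply(reports, is.character, logical(1))
  agg <- list()
  tasks <- unique(vapply(trials[!failed], function(tr) tr$manifest$task, ""))
  for (task in tasks) {
    sel <- !failed & vapply(trials, function(tr) tr$manifest$task == task, logical(1))
    for (mode in c("marker", "coordinate", "inverse")) {
      vals <- unlist(lapply(reports[sel], function(rp) {
        mo <- rp$modes[[mode]]
        if (is.null(mo)) return(NULL)
        mo$metrics$marker_rmsd_mm[["mean"]]
      }))
      if (length(vals))
        agg[[task]][[mode]] <- c(mean = mean(vals), sd = stats::sd(vals),
                                 n = length(vals))
    }
  }
  structure(list(reports = reports, failed = which(failed), aggregate = agg),
            class = "batch_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("trial report: %s (seed %d)\n", x$task, x$seed))
  for (mode in names(x$modes)) {
    mm <- x$modes[[mode]]$metrics$marker_rmsd_mm
    cat(sprintf("  %-10s marker RMSD %.2f +/- %.2f mm\n", mode,
                mm[["mean"]], mm[["sd"]]))
  }
  for (mode in names(x$errors))
    cat(sprintf("  %-10s FAILED: %s\n", mode, x$errors[[mode]]))
  invisible(x)
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("batch report: %d trials (%d failed)\n",
              length(x$reports), length(x$failed)))
  for (task in names(x$aggregate)) {
    for (mode in names(x$aggregate[[task]])) {
      a <- x$aggregate[[task]][[mode]]
      cat(sprintf("  %-17s %-10s marker RMSD %.2f +/- %.2f mm (n=%d)\n",
                  task, mode, a[["mean"]], a[["sd"]], a[["n"]]))
    }
  }
  invisible(x)
}
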
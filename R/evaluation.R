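# Comparison metrics: RMSD, unit scalings, residual metrics and convergence
# reporting.

#' Root mean squared deviation per signal
#'
#' @param estimated,reference matrices (frames x signals) or vectors, aligned
#'   over the motion of interest.
#' @return per-signal RMSD vector.
#' @export
rmsd <- function(estimated, reference) {
  e <- as.matrix(estimated); r <- as.matrix(reference)
  if (!identical(dim(e), dim(r)))
    stop(sprintf("length mismatch: estimated %dx%d vs reference %dx%d",
                 nrow(e), ncol(e), nrow(r), ncol(r)))
  sqrt(colMeans((e - r)^2))
}

#' Aggregate per-signal RMSDs
#'
#' Mean and sample standard deviation (ddof = 1) over all signals of one type
#' and all trials of one motion.
#'
#' @param values vector of per-signal RMSDs.
#' @return named vector `c(mean, sd, n)`.
#' @export
aggregate_rmsd <- function(values) {
  c(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Unit scalings for forces and moments
#'
#' GRFs scale to body-weight percent (BW%), joint moments to body-weight
#' body-height percent (BW BH%), residual forces to percent of the maximal
#' net ground reaction force (GRFmax%) and residual moments to GRFmax BH%.
#' Uses g = 9.81 m/s^2.
#'
#' @param value force (N) or moment (N m); vectors allowed.
#' @param kind one of `"grf"`, `"moment"`, `"residual_force"`,
#'   `"residual_moment"`.
#' @param body_mass kg.
#' @param body_height m.
#' @param grf_max maximal net GRF magnitude (N), required for residual kinds.
#' @return scaled value.
#' @export
scale_units <- function(value, kind = c("grf", "moment", "residual_force",
                                        "residual_moment"),
                        body_mass, body_height = NULL, grf_max = NULL) {
  kind <- match.arg(kind)
  g <- 9.81
  chk <- function(v, nm) if (is.null(v) || v <= 0)
    stop(sprintf("%s must be positive for kind '%s'", nm, kind))
  switch(kind,
    grf = { chk(body_mass, "body_mass"); 100 * value / (body_mass * g) },
    moment = { chk(body_mass, "body_mass"); chk(body_height, "body_height")
      100 * value / (body_mass * g * body_height) },
    residual_force = { chk(grf_max, "grf_max"); 100 * value / grf_max },
    residual_moment = { chk(grf_max, "grf_max"); chk(body_height, "body_height")
      100 * value / (grf_max * body_height) })
}

#' Maximal net ground reaction force
#'
#' Maximum over the motion of interest of the magnitude of the vector sum of
#' both feet's GRFs.
#'
#' @param grf N x 6 matrix (right Fx,Fy,Fz, left Fx,Fy,Fz) in N.
#' @return scalar (N).
#' @export
grf_max_net <- function(grf) {
  net <- grf[, 1:3, drop = FALSE] + grf[, 4:6, drop = FALSE]
  max(sqrt(rowSums(net^2)))
}

#' Residual force and moment metrics
#'
#' For a reconstruction, the a-posteriori violations of the multibody
#' dynamics constraints are the residual pelvis forces, pelvis moments and
#' joint moments; for inverse dynamics, the 6-DoF pelvis imbalance. RMS is
#' taken over the motion of interest and scaled to GRFmax% (forces) and
#' GRFmax BH% (moments).
#'
#' @param result an `msk_recon` or `msk_id` object.
#' @param model the `msk_model` (taken from the result when present).
#' @param grf_max maximal net GRF (N) over the motion of interest.
#' @param moi motion-of-interest span `c(start, end)` (half-open node range);
#'   defaults to the tracked data's span for reconstructions, all frames for
#'   inverse dynamics.
#' @return named list with RMS residual pelvis forces (`pelvis_force_grfmax_pct`),
#'   pelvis moments (`pelvis_moment_grfmax_bh_pct`) and, for reconstructions,
#'   joint moments (`joint_moment_grfmax_bh_pct`), plus the raw RMS values in
#'   N and N m.
#' @export
residual_metrics <- function(result, model = NULL, grf_max, moi = NULL) {
  UseMethod("residual_metrics")
}

#' @export
residual_metrics.msk_recon <- function(result, model = NULL, grf_max, moi = NULL) {
  model <- if (is.null(model)) result$model else model
  if (is.null(moi)) moi <- result$data$moi
  nd <- n_dof(model); nf <- n_residual(model)
  traj <- result$trajectory
  cc <- dynamics_constraints(traj, model)
  blocks <- matrix(cc[seq_len((traj$N - 1) * nf)], nrow = nf)  # block k -> node k+1
  nodes <- pmax(moi_rows(moi) - 1, 1)  # block indices covering the moi nodes
  mb <- blocks[nd + seq_len(nd), nodes, drop = FALSE]
  rms <- function(m) sqrt(mean(m^2))
  f_rms <- rms(mb[1:3, ]); m_rms <- rms(mb[4:6, ])
  jm_rms <- rms(mb[7:nd, ])
  list(pelvis_force_n = f_rms, pelvis_moment_nm = m_rms, joint_moment_nm = jm_rms,
       pelvis_force_grfmax_pct = scale_units(f_rms, "residual_force",
                                             model$body_mass, grf_max = grf_max),
       pelvis_moment_grfmax_bh_pct = scale_units(m_rms, "residual_moment",
                                                 model$body_mass,
                                                 model$body_height, grf_max),
       joint_moment_grfmax_bh_pct = scale_units(jm_rms, "residual_moment",
                                                model$body_mass,
                                                model$body_height, grf_max))
}

#' @export
residual_metrics.msk_id <- function(result, model = NULL, grf_max, moi = NULL) {
  if (is.null(model)) stop("inverse-dynamics residual metrics need the model")
  rows <- if (is.null(moi)) seq_len(nrow(result$residual_forces)) else moi_rows(moi)
  rms <- function(m) sqrt(mean(m^2))
  f_rms <- rms(result$residual_forces[rows, , drop = FALSE])
  m_rms <- rms(result$residual_moments[rows, , drop = FALSE])
  list(pelvis_force_n = f_rms, pelvis_moment_nm = m_rms,
       pelvis_force_grfmax_pct = scale_units(f_rms, "residual_force",
                                             model$body_mass, grf_max = grf_max),
       pelvis_moment_grfmax_bh_pct = scale_units(m_rms, "residual_moment",
                                                 model$body_mass,
                                                 model$body_height, grf_max))
}

#' Convergence report
#'
#' Extracts the convergence table fields (iterations, scaled NLP error, wall
#' time, CPU time, CPU time per iteration, share of CPU time spent in the NLP
#' function evaluations) from a solved reconstruction, or parses them from a
#' `key: value` text log.
#'
#' @param x an `msk_recon` object or a character vector of log lines.
#' @return named list of convergence fields.
#' @export
convergence_report <- function(x) UseMethod("convergence_report")

#' @export
convergence_report.msk_recon <- function(x) {
  cv <- x$convergence
  list(iterations = cv$iterations, scaled_nlp_error = cv$scaled_nlp_error,
       wall_time_s = cv$wall_time_s, cpu_time_s = cv$cpu_time_s,
       cpu_per_iteration_s = cv$cpu_time_s / max(1, cv$iterations),
       nlp_eval_share_pct = cv$nlp_eval_share_pct)
}

#' @export
convergence_report.character <- function(x) {
  out <- list()
  for (l in x) {
    if (!nzchar(trimws(l))) next
    if (!grepl(":", l, fixed = TRUE))
      stop(sprintf("unparseable log line: '%s'", l))
    kv <- strsplit(l, ":", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(trimws(paste(kv[-1], collapse = ":"))))
    if (is.na(val)) stop(sprintf("unparseable log line: '%s'", l))
    out[[trimws(kv[1])]] <- val
  }
  if (!is.null(out$cpu_time_s) && !is.null(out$iterations))
    out$cpu_per_iteration_s <- out$cpu_time_s / max(1, out$iterations)
  if (!is.null(out$nlp_cpu_s) && !is.null(out$cpu_time_s))
    out$nlp_eval_share_pct <- 100 * out$nlp_cpu_s / out$cpu_time_s
  out
}
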
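# S3 methods for the solver result classes.

#' @export
print.msk_recon <- function(x, ...) {
  cat(sprintf("%s-tracking reconstruction (%s)\n", x$mode,
              x$convergence$status))
  cat(sprintf("  %d nodes, T = %.3f s, h = %.2f ms\n",
              x$trajectory$N, x$trajectory$T, 1000 * x$trajectory$h))
  cat(sprintf("  objective %.6g = tracking %.4g + muscle %.4g + torque %.4g + reg %.4g\n",
              x$objective, x$breakdown["tracking"], x$breakdown["muscular_effort"],
              x$breakdown["torque_effort"], x$breakdown["regularization"]))
  cat(sprintf("  max dynamics violation %.3g, scaled NLP error %.3g\n",
              x$max_violation, x$convergence$scaled_nlp_error))
  cat(sprintf("  %d iterations, wall %.1f s, CPU %.1f s (%.1f%% in NLP evaluations)\n",
              x$convergence$iterations, x$convergence$wall_time_s,
              x$convergence$cpu_time_s, x$convergence$nlp_eval_share_pct))
  invisible(x)
}

#' @export
summary.msk_recon <- function(object, ...) {
  yhat <- fitted(object)
  out <- list(mode = object$mode, objective = object$objective,
              breakdown = object$breakdown,
              max_violation = object$max_violation,
              convergence = convergence_report(object),
              tracking_rmsd = lapply(names(object$data$types), function(j) {
                rows <- moi_rows(object$data$moi)
                aggregate_rmsd(rmsd(yhat[[j]][rows, , drop = FALSE],
                                    object$data$types[[j]]$y[rows, , drop = FALSE]))
              }))
  names(out$tracking_rmsd) <- names(object$data$types)
  class(out) <- "summary.msk_recon"
  out
}

#' @export
print.summary.msk_recon <- function(x, ...) {
  cat(sprintf("%s-tracking reconstruction, objective %.6g (max violation %.2g)\n",
              x$mode, x$objective, x$max_violation))
  units <- c(marker = "mm", translation = "mm", angle = "deg", grf = "BW%")
  for (j in names(x$tracking_rmsd)) {
    a <- x$tracking_rmsd[[j]]
    cat(sprintf("  %-12s RMSD %.2f +/- %.2f %s (%d signals, motion of interest)\n",
                j, a["mean"], a["sd"], units[[j]], a["n"]))
  }
  cv <- x$convergence
  cat(sprintf("  %d iterations, scaled NLP error %.2g, CPU %.1f s\n",
              cv$iterations, cv$scaled_nlp_error, cv$cpu_time_s))
  invisible(x)
}

#' Predicted tracking signals of a reconstruction
#'
#' @param object an `msk_recon`.
#' @param ... unused.
#' @return named list of predicted signal matrices in tracking units.
#' @export
fitted.msk_recon <- function(object, ...) {
  predicted_signals(object$model, object$trajectory$X, names(object$data$types))
}

#' Residuals of a reconstruction
#'
#' @param object an `msk_recon`.
#' @param type `"dynamics"` for the collocation constraint residuals (matrix,
#'   residual rows x intervals), or `"tracking"` for reference minus
#'   predicted signals per type.
#' @param ... unused.
#' @export
residuals.msk_recon <- function(object, type = c("dynamics", "tracking"), ...) {
  type <- match.arg(type)
  if (type == "dynamics") {
    nf <- n_residual(object$model)
    cc <- dynamics_constraints(object$trajectory, object$model)
    m <- matrix(cc[seq_len((object$trajectory$N - 1) * nf)], nrow = nf)
    rownames(m) <- dyn_residual_names(object$model)
    m
  } else {
    yhat <- fitted(object)
    lapply(stats::setNames(names(object$data$types), names(object$data$types)),
           function(j) object$data$types[[j]]$y - yhat[[j]])
  }
}

#' Plot tracked against reference signals
#'
#' @param x an `msk_recon`.
#' @param type data type to plot.
#' @param signals column indices to show.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.msk_recon <- function(x, type = names(x$data$types)[1],
                           signals = 1:min(6, ncol(x$data$types[[type]]$y)), ...) {
  yhat <- fitted(x)[[type]][, signals, drop = FALSE]
  y <- x$data$types[[type]]$y[, signals, drop = FALSE]
  units <- c(marker = "mm", translation = "mm", angle = "deg", grf = "BW%")
  graphics::matplot(x$trajectory$times, y, type = "l", lty = 1,
                    xlab = "time [s]", ylab = sprintf("%s [%s]", type, units[[type]]),
                    ...)
  graphics::matlines(x$trajectory$times, yhat, lty = 2)
  graphics::abline(v = x$trajectory$times[x$data$moi[1]], col = "gray")
  graphics::legend("topright", c("reference", "reconstruction"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' @export
print.msk_standing <- function(x, ...) {
  cat(sprintf("standing calibration (%s tracking): objective %.6g\n",
              x$mode, x$objective))
  cat(sprintf("  contact offset %.2f mm, max equilibrium violation %.2g\n",
              1000 * x$offset, x$max_violation))
  cat(sprintf("  restart %d of %d selected (seed %d); converged: %d\n",
              x$restarts$selected, x$restarts$n, x$restarts$seed,
              sum(x$restarts$status == "converged")))
  invisible(x)
}

#' @export
print.msk_ik <- function(x, ...) {
  cat(sprintf("inverse kinematics: %d frames at %g Hz\n", nrow(x$Q), x$rate))
  cat(sprintf("  marker residual RMS %.2f +/- %.2f mm\n",
              mean(x$resid_rms_mm), stats::sd(x$resid_rms_mm)))
  invisible(x)
}

#' @export
print.msk_id <- function(x, ...) {
  cat(sprintf("inverse dynamics: %d frames at %g Hz\n",
              nrow(x$joint_moments), x$rate))
  rms <- function(m) sqrt(mean(m^2))
  cat(sprintf("  RMS residual pelvis force %.2f N, moment %.2f N m\n",
              rms(x$residual_forces), rms(x$residual_moments)))
  invisible(x)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("synthetic %s trial (seed %d)\n", x$manifest$task, x$manifest$seed))
  cat(sprintf("  %d nodes (%d lead-in + %d motion of interest) at %g Hz\n",
              x$truth$N, x$manifest$n_pre, x$manifest$N_moi, x$markers$rate))
  cat(sprintf("  marker noise %.1f mm, artifact %.1f mm @ %.1f Hz, sole offset %.1f mm\n",
              x$manifest$corruption$marker_sd_mm, x$manifest$corruption$sta_amp_mm,
              x$manifest$corruption$sta_freq_hz, x$manifest$corruption$sole_offset_mm))
  invisible(x)
}
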
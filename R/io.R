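# Motion-capture file formats (TRC markers, STO/MOT tables), recording
# containers, gait-event detection and motion-of-interest extraction.

#' Marker recording container
#'
#' @param names marker names.
#' @param rate sampling rate (Hz).
#' @param pos N x (3 * n_markers) matrix of positions (mm), marker-major
#'   (x1, y1, z1, x2, ...).
#' @param mask N x n_markers logical validity matrix (FALSE = occluded).
#' @param units position unit string.
#' @return object of class `marker_recording`.
#' @export
marker_recording <- function(names, rate, pos, mask = NULL, units = "mm") {
  pos <- as.matrix(pos)
  if (rate <= 0) stop("sampling rate must be positive")
  if (ncol(pos) != 3 * length(names))
    stop("positions must have 3 columns per marker")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pos), length(names))
  if (!identical(dim(mask), c(nrow(pos), length(names))))
    stop("mask shape does not match positions")
  structure(list(names = names, rate = rate, pos = pos, mask = mask,
                 units = units), class = "marker_recording")
}

#' Force-plate recording container
#'
#' @param rate sampling rate (Hz).
#' @param plates list per plate of `force` (N x 3, N), `cop` (N x 3, m) and
#'   `moment` (N x 3, N m; free moment).
#' @return object of class `forceplate_recording`.
#' @export
forceplate_recording <- function(rate, plates) {
  if (rate <= 0) stop("sampling rate must be positive")
  plates <- lapply(plates, function(p) {
    p$force <- as.matrix(p$force); p$cop <- as.matrix(p$cop)
    p$moment <- as.matrix(p$moment)
    p
  })
  structure(list(rate = rate, plates = plates), class = "forceplate_recording")
}

#' Write a marker recording as TRC
#'
#' Tab-separated TRC dialect with the usual header rows (PathFileType,
#' DataRate/NumFrames/Units). Occluded samples are written as blank cells.
#'
#' @param rec a [marker_recording()].
#' @param path output file.
#' @param digits decimal places for positions.
#' @return `path`, invisibly.
#' @export
write_trc <- function(rec, path, digits = 5) {
  nmk <- length(rec$names); n <- nrow(rec$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                   "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
                     rec$rate, rec$rate, n, nmk, rec$units, rec$rate, n), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(rec$names, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), nmk),
                                    rep(seq_len(nmk), each = 3))), collapse = "\t"), con)
  writeLines("", con)
  fmt <- sprintf("%%.%df", digits)
  for (k in seq_len(n)) {
    vals <- sprintf(fmt, rec$pos[k, ])
    occ <- rep(!rec$mask[k, ], each = 3)
    vals[occ] <- ""
    writeLines(paste(c(sprintf("%d", k), sprintf("%.6f", (k - 1) / rec$rate), vals),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path TRC file.
#' @return a [marker_recording()]; blank cells become occlusion-mask entries.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "PathFileType"))
    stop(sprintf("%s: line 1: not a TRC file (missing PathFileType)", path))
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  if (length(vals) < length(keys))
    stop(sprintf("%s: line 3: expected %d header values, found %d",
                 path, length(keys), length(vals)))
  hd <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(hd$DataRate)
  nmk <- as.integer(hd$NumMarkers)
  units <- hd$Units
  names_row <- strsplit(lines[4], "\t")[[1]]
  mknames <- names_row[seq(3, by = 3, length.out = nmk)]
  first_data <- 7
  while (first_data <= length(lines) && !nzchar(trimws(lines[first_data])))
    first_data <- first_data + 1
  data_lines <- lines[seq(first_data, length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  pos <- matrix(NA_real_, n, 3 * nmk)
  for (k in seq_len(n)) {
    cells <- strsplit(data_lines[k], "\t")[[1]]
    if (length(cells) < 2)
      stop(sprintf("%s: data line %d: too few columns", path, k))
    cells <- c(cells, rep("", 2 + 3 * nmk - length(cells)))
    v <- cells[3:(2 + 3 * nmk)]
    blank <- !nzchar(trimws(v))
    pos[k, ] <- suppressWarnings(as.numeric(replace(v, blank, NA)))
    if (any(is.na(pos[k, ]) & !blank))
      stop(sprintf("%s: data line %d: non-numeric marker value", path, k))
  }
  mask <- !is.na(pos[, seq(1, 3 * nmk, by = 3), drop = FALSE])
  pos[is.na(pos)] <- 0
  marker_recording(mknames, rate, pos, mask, units)
}

#' Write a data frame as an STO/MOT table
#'
#' @param df data frame whose first column is `time`.
#' @param path output file.
#' @param name table name written in the header.
#' @param metadata named list of extra `key=value` header entries (for
#'   example `inDegrees`, filter settings, rates).
#' @return `path`, invisibly.
#' @export
write_sto <- function(df, path, name = basename(path), metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(name, con)
  writeLines("version=1", con)
  writeLines(sprintf("nRows=%d", nrow(df)), con)
  writeLines(sprintf("nColumns=%d", ncol(df)), con)
  for (k in names(metadata)) writeLines(sprintf("%s=%s", k, metadata[[k]]), con)
  writeLines("endheader", con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an STO/MOT table
#'
#' @param path file with a `endheader`-terminated header.
#' @return list with `data` (data frame), `name` and `metadata`.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0)
    stop(sprintf("%s: no 'endheader' line found", path))
  end <- end[1]
  meta <- list()
  for (l in lines[seq_len(end - 1)][-1]) {
    if (grepl("=", l, fixed = TRUE)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  header <- strsplit(lines[end + 1], "\t")[[1]]
  dat <- utils::read.table(text = lines[seq(end + 2, length(lines))],
                           sep = "\t", col.names = header, check.names = FALSE)
  list(data = dat, name = lines[1], metadata = meta)
}

#' Write a force-plate recording as STO
#'
#' @param rec a [forceplate_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grf_sto <- function(rec, path) {
  n <- nrow(rec$plates[[1]]$force)
  df <- data.frame(time = (seq_len(n) - 1) / rec$rate)
  for (p in seq_along(rec$plates)) {
    pl <- rec$plates[[p]]
    for (comp in c("force", "cop", "moment")) {
      tag <- c(force = "f", cop = "p", moment = "m")[[comp]]
      m <- pl[[comp]]
      colnames(m) <- sprintf("%s%d_%s", tag, p, c("x", "y", "z"))
      df <- cbind(df, m)
    }
  }
  write_sto(df, path, name = "ground reaction forces",
            metadata = list(dataRate = sprintf("%g", rec$rate)))
}

#' Read a force-plate STO written by [write_grf_sto()]
#'
#' @param path STO file.
#' @return a [forceplate_recording()].
#' @export
read_grf_sto <- function(path) {
  sto <- read_sto(path)
  rate <- as.numeric(sto$metadata$dataRate)
  plates <- list()
  p <- 1
  while (sprintf("f%d_x", p) %in% names(sto$data)) {
    plates[[p]] <- list(
      force = as.matrix(sto$data[sprintf("f%d_%s", p, c("x", "y", "z"))]),
      cop = as.matrix(sto$data[sprintf("p%d_%s", p, c("x", "y", "z"))]),
      moment = as.matrix(sto$data[sprintf("m%d_%s", p, c("x", "y", "z"))]))
    plates[[p]] <- lapply(plates[[p]], unname)
    p <- p + 1
  }
  forceplate_recording(rate, plates)
}

#' Decimate a force-plate recording to the kinematic rate
#'
#' Integer-factor decimation keeping the first sample aligned with the first
#' marker frame. No anti-alias filtering is applied: simulation reference
#' data are tracked unfiltered, and the inverse-dynamics pathway applies its
#' own low-pass filter anyway. Set `prefilter_hz` for an optional dual-pass
#' Butterworth before decimation.
#'
#' @param rec a [forceplate_recording()].
#' @param target_hz target rate; the source rate must be an integer multiple.
#' @param prefilter_hz optional low-pass cutoff before decimation (Hz).
#' @return a [forceplate_recording()] at `target_hz`.
#' @export
downsample_grf <- function(rec, target_hz, prefilter_hz = NULL) {
  fac <- rec$rate / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop(sprintf("source rate %g Hz is not an integer multiple of %g Hz",
                 rec$rate, target_hz))
  fac <- as.integer(round(fac))
  if (fac == 1L && is.null(prefilter_hz)) return(rec)
  plates <- lapply(rec$plates, function(pl) {
    lapply(pl, function(m) {
      if (!is.null(prefilter_hz))
        m <- butterworth_dualpass(m, prefilter_hz, rec$rate)
      m[seq(1, nrow(m), by = fac), , drop = FALSE]
    })
  })
  forceplate_recording(target_hz, plates)
}

#' Detect initial contact from heel and toe markers
#'
#' The initial-contact frame is where the vertical velocity of the mean of
#' the heel and toe marker positions is at its minimum (central differences;
#' one-sided at the edges). Ties return the earliest frame.
#'
#' @param heel,toe N x 3 position matrices (or vertical-component vectors).
#' @param rate sampling rate (Hz).
#' @param vertical column index of the vertical axis (default 2 = Y).
#' @param window optional `c(first, last)` frame range to search.
#' @return frame index (1-based) of the initial contact.
#' @export
detect_initial_contact <- function(heel, toe, rate = 1, vertical = 2,
                                   window = NULL) {
  hv <- if (is.matrix(heel)) heel[, vertical] else heel
  tv <- if (is.matrix(toe)) toe[, vertical] else toe
  if (length(hv) != length(tv)) stop("heel and toe series differ in length")
  n <- length(hv)
  if (n < 3) stop("need at least 3 frames")
  m <- (hv + tv) / 2
  vel <- c(m[2] - m[1], (m[3:n] - m[1:(n - 2)]) / 2, m[n] - m[n - 1]) * rate
  if (max(m) - min(m) < 1e-12)
    stop("ambiguous event: vertical trajectory is constant (zero velocity everywhere)")
  idx <- seq_len(n)
  if (!is.null(window)) idx <- idx[idx >= window[1] & idx <= window[2]]
  idx[which.min(vel[idx])]
}

#' Extract the motion of interest from initial-contact events
#'
#' The analyzed span runs from one right-foot initial contact to the next,
#' half-open `[IC1, IC2)`. Extraction is applied after reconstruction; the
#' reconstruction itself additionally spans the lead-in context samples.
#'
#' @param events sorted right-foot initial-contact frame indices (at least 2).
#' @return integer vector `c(start, end)`, half-open.
#' @export
extract_motion_of_interest <- function(events) {
  if (length(events) < 2)
    stop(sprintf("need at least 2 initial-contact events, got %d", length(events)))
  events <- sort(as.integer(events))
  c(start = events[1], end = events[2])
}

moi_rows <- function(moi) seq(moi[1], moi[2] - 1)
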
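#' Framewise motion summaries
#'
#' Frame-to-frame displacement: the Euclidean norm of the successive
#' differences of the three translations (mm) and, separately, of the
#' three rotations (degrees).  Also reports the peak absolute excursion
#' of any single parameter from the run's reference (first) volume, the
#' alignment-target convention used for run exclusion.
#'
#' @param trace Volumes x 6 matrix: x, y, z (mm), pitch, roll, yaw (deg).
#' @return List: `mean_xyz`, `max_xyz`, `mean_angular`, `max_angular`
#'   (framewise), `ref_max_xyz`, `ref_max_angular` (from-reference), and
#'   `framewise` (per-frame data.frame).
#' @export
framewise_motion <- function(trace) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("motion trace needs at least 2 volumes")
  if (ncol(trace) != 6) stop("motion trace must have 6 columns")
  d <- diff(trace)
  fd_xyz <- sqrt(rowSums(d[, 1:3, drop = FALSE]^2))
  fd_ang <- sqrt(rowSums(d[, 4:6, drop = FALSE]^2))
  ref <- sweep(trace, 2, trace[1, ])
  list(mean_xyz = mean(fd_xyz), max_xyz = max(fd_xyz),
       mean_angular = mean(fd_ang), max_angular = max(fd_ang),
       ref_max_xyz = max(abs(ref[, 1:3])),
       ref_max_angular = max(abs(ref[, 4:6])),
       framewise = data.frame(xyz = fd_xyz, angular = fd_ang))
}

#' Standardized DVARS
#'
#' Raw DVARS at frame t is the root-mean-square over in-mask voxels of
#' the volume-to-volume intensity difference.  Standardization divides by
#' its predicted value under temporally independent noise: the
#' root-mean-square of the voxelwise robust SDs of the differenced
#' series, with robust SD = IQR / 1.349 (the IQR of a standard normal).
#' Clean, temporally independent data therefore scores about 1.
#'
#' @param run A `bold_run` or a volumes x voxels matrix.
#' @param mask Optional logical selector of voxels (default: all voxels
#'   with nonzero variance).
#' @return List: `series` (length volumes - 1), `mean`, `max`.
#' @export
standardized_dvars <- function(run, mask = NULL) {
  Y <- if (inherits(run, "bold_run")) {
    t(matrix(run$data, nrow = prod(dim(run$data)[1:3])))
  } else as.matrix(run)
  nv <- nrow(Y)
  if (nv < 3) stop("standardized DVARS needs at least 3 volumes")
  default_mask <- is.null(mask)
  if (default_mask) mask <- apply(Y, 2, stats::var) > 0
  mask <- as.logical(mask)
  if (!any(mask)) {
    if (default_mask) stop("constant run: predicted DVARS is zero")
    stop("mask is empty")
  }
  D <- diff(Y[, mask, drop = FALSE])
  rsd <- apply(D, 2, stats::IQR) / 1.349
  pred <- sqrt(mean(rsd^2))
  if (pred == 0) stop("constant run: predicted DVARS is zero")
  series <- sqrt(rowMeans(D^2)) / pred
  list(series = series, mean = mean(series), max = max(series))
}

#' Assemble a per-run quality-control report
#'
#' @param motion Volumes x 6 motion trace.
#' @param run Optional `bold_run` (for DVARS).
#' @param events Optional [event_table()] (for response accuracy over
#'   target trials).
#' @param mask Optional DVARS voxel mask.
#' @return Object of class `qc_report`: one-row data.frame with
#'   `mean_xyz, max_xyz, mean_angular, max_angular, ref_max_xyz,
#'   ref_max_angular, mean_dvars, max_dvars, accuracy, excluded,
#'   exclusion_reasons` (reasons as a `;`-separated string, empty when
#'   retained).  `excluded` is `NA` until [run_exclusion()] is applied.
#' @export
qc_report <- function(motion, run = NULL, events = NULL, mask = NULL) {
  fm <- framewise_motion(motion)
  dv <- if (!is.null(run)) standardized_dvars(run, mask) else
    list(mean = NA_real_, max = NA_real_)
  acc <- NA_real_
  if (!is.null(events)) {
    tgt <- events$trial_type %in% event_conditions()
    if (any(tgt)) acc <- mean(events$accuracy[tgt], na.rm = TRUE)
  }
  out <- data.frame(mean_xyz = fm$mean_xyz, max_xyz = fm$max_xyz,
                    mean_angular = fm$mean_angular,
                    max_angular = fm$max_angular,
                    ref_max_xyz = fm$ref_max_xyz,
                    ref_max_angular = fm$ref_max_angular,
                    mean_dvars = dv$mean, max_dvars = dv$max,
                    accuracy = acc, excluded = NA,
                    exclusion_reasons = "", stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Apply the run-exclusion rules
#'
#' A run is excluded when its peak displacement from the reference volume
#' exceeds 3 mm or 3 degrees, or when fewer than two thirds of target
#' responses are correct.  No interpolation or scrubbing is ever applied;
#' exclusion is all-or-none per run.
#'
#' @param qc A [qc_report()].
#' @param accuracy Optional accuracy override (defaults to `qc$accuracy`).
#' @param motion_limits Length-2: translation limit (mm), rotation limit
#'   (degrees); default `c(3, 3)`.
#' @param accuracy_floor Minimum proportion correct (default 2/3).
#' @return The report with `excluded` and `exclusion_reasons` filled in.
#' @export
run_exclusion <- function(qc, accuracy = NULL, motion_limits = c(3, 3),
                          accuracy_floor = 2 / 3) {
  stopifnot(inherits(qc, "qc_report"))
  if (is.null(accuracy)) accuracy <- qc$accuracy
  reasons <- character(0)
  mx <- if (is.finite(qc$ref_max_xyz)) qc$ref_max_xyz else qc$max_xyz
  ma <- if (is.finite(qc$ref_max_angular)) qc$ref_max_angular else qc$max_angular
  if (mx > motion_limits[1] || ma > motion_limits[2])
    reasons <- c(reasons, "motion")
  if (is.finite(accuracy) && accuracy < accuracy_floor)
    reasons <- c(reasons, "accuracy")
  qc$accuracy <- accuracy
  qc$excluded <- length(reasons) > 0
  qc$exclusion_reasons <- paste(reasons, collapse = ";")
  qc
}

#' Write QC reports as TSV
#' @param reports A `qc_report` or list of them (rows are bound).
#' @param path Output file.
#' @export
write_qc_tsv <- function(reports, path) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
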
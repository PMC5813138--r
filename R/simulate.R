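#' Cohort specification for the synthetic study
#'
#' Defines the geometry of a simulated two-group event-related fMRI study:
#' group sizes, runs per subject, run length and repetition time.  Defaults
#' mirror a 5-minute acquisition at TR 1.92 s (156 volumes) with six runs
#' per subject.
#'
#' @param n_control,n_patient Number of subjects per group (each >= 2).
#' @param runs_per_subject Runs acquired per subject (default 6).
#' @param run_duration Run length in seconds (default 300).
#' @param tr Repetition time in seconds (default 1.92).
#' @param seed Integer seed from which all per-subject, per-run random
#'   streams are derived deterministically.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_patient, runs_per_subject = 6,
                        run_duration = 300, tr = 1.92, seed = 1L) {
  stopifnot(n_control >= 2, n_patient >= 2, runs_per_subject >= 1,
            run_duration > 0, tr > 0)
  if (run_duration / tr < 10)
    stop("run_duration/tr must allow at least 10 volumes")
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 runs_per_subject = as.integer(runs_per_subject),
                 run_duration = run_duration, tr = tr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Number of volumes implied by a cohort specification
#' @param spec A [cohort_spec()].
#' @return Integer, `floor(run_duration / tr)`.
#' @export
n_volumes <- function(spec) as.integer(floor(spec$run_duration / spec$tr))

#' Group-by-condition reaction-time model
#'
#' Per group and flanker condition: the arithmetic mean and SD of the
#' reaction-time distribution (milliseconds) and the probability of a
#' correct response.  RTs are drawn from a lognormal reparameterised to
#' the given arithmetic mean/SD (reaction times are positive and
#' right-skewed).  The default values are the study conditions: control
#' means 714/1005/1084 ms (SD 121/217/265) and patient means
#' 1125/1521/1800 ms (SD 262/391/486) for congruent / easy-incongruent /
#' hard-incongruent trials.
#'
#' @param rt_mean,rt_sd 2 x 3 numeric matrices (rows `control`, `patient`;
#'   columns the three conditions), milliseconds.
#' @param accuracy 2 x 3 matrix of correct-response probabilities.
#' @return Object of class `rt_model`.
#' @export
rt_model <- function(rt_mean, rt_sd, accuracy) {
  gr <- c("control", "patient"); cond <- event_conditions()
  chk <- function(m, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(2, 3)))
      stop(nm, " must be a 2 x 3 group-by-condition matrix")
    dimnames(m) <- list(gr, cond)
    m
  }
  rt_mean <- chk(rt_mean, "rt_mean"); rt_sd <- chk(rt_sd, "rt_sd")
  accuracy <- chk(accuracy, "accuracy")
  stopifnot(all(rt_mean > 0), all(rt_sd > 0),
            all(accuracy > 0), all(accuracy <= 1))
  # difficulty ordering within each group
  if (any(apply(rt_mean, 1, diff) < 0))
    stop("rt_mean must be non-decreasing from congruent to hard incongruent")
  structure(list(rt_mean = rt_mean, rt_sd = rt_sd, accuracy = accuracy),
            class = "rt_model")
}

#' @rdname rt_model
#' @export
default_rt_model <- function() {
  rt_model(rt_mean = rbind(control = c(714, 1005, 1084),
                           patient = c(1125, 1521, 1800)),
           rt_sd = rbind(control = c(121, 217, 265),
                         patient = c(262, 391, 486)),
           accuracy = rbind(control = c(0.97, 0.93, 0.90),
                            patient = c(0.92, 0.87, 0.82)))
}

# lognormal parameters for a target arithmetic mean/sd
.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# deterministic per-(subject, run) random stream; keeps seeds < 2^31
.stream_seed <- function(seed, subject, run, salt = 0L) {
  as.integer((as.double(seed) * 7919 + subject * 104729 +
                run * 1299709 + salt * 15485863) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate the trial sequence of one run
#'
#' Each trial is a cue followed after a fixed gap by a flanker target;
#' condition is sampled uniformly from the three target conditions, the
#' reaction time from the group-by-condition lognormal, and correctness
#' from a Bernoulli with the configured accuracy.  Inter-trial intervals
#' are uniform on `iti_range` and start only after the response, so events
#' never overlap responses.  Roughly 20-30 trials fit in a 300 s run with
#' the default 8-12 s spacing.
#'
#' @param spec A [cohort_spec()].
#' @param model An [rt_model()].
#' @param group `"control"` or `"patient"`.
#' @param subject,run Integer indices identifying the random stream.
#' @param iti_range Uniform inter-trial interval bounds in seconds
#'   (response offset to next cue), default `c(8, 12)`.
#' @param cue_gap Cue-to-target interval in seconds: either a fixed value
#'   or a `c(min, max)` range sampled uniformly per trial (default
#'   `c(0.5, 1.5)`).  The jitter decorrelates the cue regressors from the
#'   target basis set -- with a fixed gap the cue column is almost exactly
#'   a combination of the target canonical and derivative columns and the
#'   design becomes near-singular.
#' @return An [event_table()] with `cue` and target rows.
#' @export
simulate_trials <- function(spec, model = default_rt_model(), group,
                            subject = 1L, run = 1L,
                            iti_range = c(8, 12), cue_gap = c(0.5, 1.5)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "rt_model"),
            group %in% c("control", "patient"))
  if (length(cue_gap) == 1) cue_gap <- rep(cue_gap, 2)
  .with_seed(.stream_seed(spec$seed, subject, run), {
    cond <- event_conditions()
    # generous bound: longest plausible trial footprint
    max_rt_s <- max(model$rt_mean[group, ] + 6 * model$rt_sd[group, ]) / 1000
    rows <- list(); t <- stats::runif(1, iti_range[1] / 2, iti_range[2] / 2)
    repeat {
      tgt_on <- t + stats::runif(1, cue_gap[1], cue_gap[2])
      cnd <- sample(cond, 1L)
      p <- .lnorm_pars(model$rt_mean[group, cnd], model$rt_sd[group, cnd])
      rt <- stats::rlnorm(1, p$meanlog, p$sdlog)
      if (tgt_on + max_rt_s + 1 >= spec$run_duration ||
          tgt_on + rt / 1000 + 1 >= spec$run_duration) break
      acc <- stats::rbinom(1, 1, model$accuracy[group, cnd])
      rows[[length(rows) + 1L]] <- data.frame(
        onset = c(t, tgt_on), duration = 0,
        trial_type = c("cue", cnd),
        response_time = c(NA_real_, rt),
        accuracy = c(NA_real_, acc))
      t <- tgt_on + rt / 1000 + stats::runif(1, iti_range[1], iti_range[2])
    }
    if (!length(rows))
      stop("run too short to place a single trial")
    ev <- do.call(rbind, rows)
    event_table(ev$onset, ev$duration, ev$trial_type,
                ev$response_time, ev$accuracy, spec$run_duration)
  })
}

#' Canonical ROI label names
#'
#' The nine regions analysed: five task-positive association regions, the
#' two default-mode components, motor cortex and basal ganglia.
#' @return Character vector of length 9.
#' @export
roi_names <- function() {
  c("mid_frontal", "lateral_frontal", "insula", "parietal", "occipital",
    "pDMN", "fDMN", "motor", "BG")
}

#' Build disjoint cuboid ROI masks on a voxel grid
#'
#' Places `n_rois` disjoint 3 x 3 x 3 voxel blocks (27 voxels each) on the
#' grid, assigning block positions in a seeded random order.  Stands in
#' for anatomically defined region masks; files written from it are
#' synthetic labels, not anatomy.
#'
#' @param grid_shape Integer length-3 voxel grid dimensions
#'   (default `c(24, 24, 12)` at a notional 3 mm isotropic).
#' @param n_rois Number of regions (default 9).
#' @param names Region names (defaults to [roi_names()]).
#' @param seed Integer seed for block placement.
#' @return Object of class `roi_mask_set`: list with `labels` (3-D integer
#'   array, 0 = background), `names`, and `grid_shape`.
#' @export
make_roi_masks <- function(grid_shape = c(24, 24, 12), n_rois = 9,
                           names = NULL, seed = 1L) {
  stopifnot(length(grid_shape) == 3, n_rois >= 1)
  if (is.null(names)) {
    names <- if (n_rois == 9) roi_names() else paste0("roi", seq_len(n_rois))
  }
  stopifnot(length(names) == n_rois)
  b <- 3L; stride <- 4L
  starts <- lapply(grid_shape, function(g) {
    if (g < b) integer(0) else seq(1L, g - b + 1L, by = stride)
  })
  origins <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  if (nrow(origins) < n_rois)
    stop("grid too small for ", n_rois, " disjoint 3x3x3 regions")
  ord <- .with_seed(as.integer(seed), sample(nrow(origins)))
  labels <- array(0L, dim = grid_shape)
  for (i in seq_len(n_rois)) {
    o <- origins[ord[i], ]
    labels[o$x:(o$x + b - 1L), o$y:(o$y + b - 1L), o$z:(o$z + b - 1L)] <- i
  }
  structure(list(labels = labels, names = names,
                 grid_shape = as.integer(grid_shape)),
            class = "roi_mask_set")
}

#' Ground-truth response parameters for one ROI
#'
#' Task-positive regions respond with an impulse at (shifted) event onset;
#' default-mode regions respond with a negative boxcar lasting from the
#' stimulus until the response (duration = that trial's RT), so their
#' fitted deactivation magnitude grows with reaction time.
#'
#' @param roi_name Region label.
#' @param response_kind `"impulse_positive"` or `"boxcar_negative"`.
#' @param amplitude 2 x 3 group-by-condition matrix (or scalar, recycled)
#'   of response amplitudes in percent signal: impulse peak height for
#'   task-positive regions, boxcar height (must be negative) for DMN.
#' @param onset_shift 2 x 3 matrix (or scalar) of onset shifts in seconds;
#'   must lie strictly inside (-1.78, 1.78), the representable range of
#'   the latency transform.
#' @param noise_sd Marginal SD of the AR(1) voxel noise, percent signal.
#' @param ar1 AR(1) coefficient in [0, 1).
#' @param drift_amplitude Amplitude of each of two slow cosine drifts
#'   (periods 192 s and 288 s), percent signal.
#' @param cue_amplitude Impulse amplitude for cue events in task-positive
#'   regions (0 for DMN).
#' @return Object of class `roi_truth`.
#' @export
roi_truth <- function(roi_name, response_kind, amplitude, onset_shift = 0,
                      noise_sd = 1, ar1 = 0.3, drift_amplitude = 1,
                      cue_amplitude = if (response_kind == "impulse_positive") 0.5 else 0) {
  response_kind <- match.arg(response_kind,
                             c("impulse_positive", "boxcar_negative"))
  gr <- c("control", "patient"); cond <- event_conditions()
  expand <- function(v) {
    m <- if (length(v) == 1) matrix(v, 2, 3) else as.matrix(v)
    stopifnot(all(dim(m) == c(2, 3)))
    dimnames(m) <- list(gr, cond); m
  }
  amplitude <- expand(amplitude); onset_shift <- expand(onset_shift)
  if (any(abs(onset_shift) >= 1.78))
    stop("onset_shift must lie strictly inside (-1.78, 1.78) s")
  if (response_kind == "boxcar_negative" && any(amplitude >= 0))
    stop("boxcar_negative amplitude must be negative")
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1, drift_amplitude >= 0)
  structure(list(roi_name = roi_name, response_kind = response_kind,
                 amplitude = amplitude, onset_shift = onset_shift,
                 noise_sd = noise_sd, ar1 = ar1,
                 drift_amplitude = drift_amplitude,
                 cue_amplitude = cue_amplitude),
            class = "roi_truth")
}

#' Default ground truth for the nine ROIs
#'
#' Task-positive amplitudes (percent signal) and onset shifts (seconds)
#' are the study's group-by-condition ROI means; DMN regions use a
#' constant negative boxcar height per group (larger in patients) with
#' zero onset shift, so condition differences in deactivation magnitude
#' emerge purely from longer reaction times.
#'
#' @param noise_sd,ar1,drift_amplitude Shared noise parameters applied to
#'   every region.
#' @return Named list of [roi_truth()] objects, one per [roi_names()].
#' @export
default_roi_truths <- function(noise_sd = 1, ar1 = 0.3, drift_amplitude = 1) {
  amp <- list(
    mid_frontal     = rbind(c(1.85, 4.07, 3.80), c(2.77, 4.87, 6.13)),
    lateral_frontal = rbind(c(0.97, 3.41, 3.40), c(1.42, 3.35, 4.72)),
    insula          = rbind(c(2.47, 5.76, 5.45), c(2.25, 3.93, 5.24)),
    parietal        = rbind(c(2.47, 5.48, 5.54), c(3.43, 6.07, 7.60)),
    occipital       = rbind(c(5.36, 8.11, 8.28), c(5.88, 7.87, 9.65)),
    motor           = rbind(c(2.87, 3.60, 3.41), c(3.03, 3.45, 3.53)),
    BG              = rbind(c(3.44, 5.47, 4.91), c(2.46, 4.11, 5.13)))
  lat <- list(
    mid_frontal     = rbind(c(-0.125, -0.249, -0.214), c(-0.119, -0.140, -0.118)),
    lateral_frontal = rbind(c(-0.094, -0.151, -0.138), c(0.024, -0.021, 0.014)),
    insula          = rbind(c(-0.030, -0.099, -0.073), c(0.011, 0.060, 0.134)),
    parietal        = rbind(c(-0.142, -0.223, -0.202), c(-0.023, -0.015, 0.123)),
    occipital       = rbind(c(-0.283, -0.234, -0.217), c(-0.117, 0.004, 0.191)),
    motor           = rbind(c(-0.452, -0.315, -0.295), c(-0.101, -0.016, 0.030)),
    BG              = rbind(c(-0.133, -0.178, -0.149), c(-0.020, 0.077, 0.040)))
  out <- list()
  for (nm in setdiff(roi_names(), c("pDMN", "fDMN"))) {
    out[[nm]] <- roi_truth(nm, "impulse_positive", amp[[nm]], lat[[nm]],
                           noise_sd = noise_sd, ar1 = ar1,
                           drift_amplitude = drift_amplitude)
  }
  out$pDMN <- roi_truth("pDMN", "boxcar_negative",
                        rbind(c(-2, -2, -2), c(-4, -4, -4)), 0,
                        noise_sd = noise_sd, ar1 = ar1,
                        drift_amplitude = drift_amplitude)
  out$fDMN <- roi_truth("fDMN", "boxcar_negative",
                        rbind(c(-1, -1, -1), c(-2.5, -2.5, -2.5)), 0,
                        noise_sd = noise_sd, ar1 = ar1,
                        drift_amplitude = drift_amplitude)
  out[roi_names()]
}

#' Simulate one 4-D BOLD run with motion trace
#'
#' Forward model, per voxel: baseline 100 plus the region's event response
#' convolved with the canonical HRF (impulse at onset + group/condition
#' onset shift for task-positive regions; negative boxcar from stimulus to
#' response for DMN regions; small fixed-amplitude cue impulses in
#' task-positive regions), plus two slow cosine drifts (periods 192 s and
#' 288 s, both beyond a 128 s high-pass cutoff), plus stationary AR(1)
#' Gaussian noise.  Background voxels carry baseline, drift and noise
#' only.  The motion trace is a smoothed random walk in the six rigid-body
#' parameters.
#'
#' @param spec A [cohort_spec()].
#' @param events An [event_table()] for this run.
#' @param truths Named list of [roi_truth()], covering every mask label.
#' @param masks A [make_roi_masks()] result.
#' @param group `"control"` or `"patient"` (selects the truth row).
#' @param subject,run Integer indices for the random stream.
#' @param motion_sd Per-step SD of the translation random walk in mm
#'   (rotations use half this value, in degrees).
#' @return List with `run` (a `bold_run`: 4-D array, tr, affine, run id),
#'   `motion` (volumes x 6 matrix) and `clean` (volumes x n_roi matrix of
#'   noiseless, drift-free ROI signals for ground-truth checks).
#' @export
simulate_run <- function(spec, events, truths, masks, group,
                         subject = 1L, run = 1L, motion_sd = 0.04) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(masks, "roi_mask_set"),
            group %in% c("control", "patient"))
  labs <- sort(setdiff(unique(as.integer(masks$labels)), 0L))
  if (!all(masks$names[labs] %in% names(truths)))
    stop("truths must cover every mask label")
  for (tr_ in truths)
    if (any(abs(tr_$onset_shift) >= 1.78))
      stop("onset_shift outside (-1.78, 1.78) is not representable")

  nv <- n_volumes(spec); os <- 16L
  dt <- spec$tr / os; ng <- nv * os
  grid_t <- (seq_len(ng) - 1) * dt
  kern <- canonical_hrf(dt)
  tgt <- events$trial_type %in% event_conditions()

  roi_signal <- function(truth) {
    imp <- numeric(ng); box <- numeric(ng)
    if (truth$response_kind == "impulse_positive") {
      for (i in which(tgt)) {
        on <- events$onset[i] + truth$onset_shift[group, events$trial_type[i]]
        j <- round(on / dt) + 1L
        if (j >= 1L && j <= ng)
          imp[j] <- imp[j] + truth$amplitude[group, events$trial_type[i]]
      }
      if (truth$cue_amplitude != 0) {
        for (i in which(events$trial_type == "cue")) {
          j <- round(events$onset[i] / dt) + 1L
          if (j >= 1L && j <= ng) imp[j] <- imp[j] + truth$cue_amplitude
        }
      }
    } else {
      for (i in which(tgt)) {
        on <- events$onset[i] + truth$onset_shift[group, events$trial_type[i]]
        j1 <- max(1L, round(on / dt) + 1L)
        j2 <- min(ng, round((on + events$response_time[i] / 1000) / dt) + 1L)
        if (j2 >= j1)
          box[j1:j2] <- box[j1:j2] + truth$amplitude[group, events$trial_type[i]]
      }
    }
    sig <- .conv_sample(imp, kern) + dt * .conv_sample(box, kern)
    sig[seq(1L, ng, by = os)]
  }

  ar1_noise <- function(n, sd, rho) {
    if (sd == 0) return(numeric(n))
    e <- stats::rnorm(n + 20L)
    x <- as.numeric(stats::filter(e, rho, method = "recursive"))
    sd * sqrt(1 - rho^2) * x[21L:(n + 20L)]
  }

  .with_seed(.stream_seed(spec$seed, subject, run, salt = 1L), {
    vol_t <- (seq_len(nv) - 1) * spec$tr
    dims <- masks$grid_shape
    dat <- array(0, dim = c(dims, nv))
    nvox <- prod(dims)
    flat <- matrix(0, nrow = nv, ncol = nvox)
    lab_vec <- as.integer(masks$labels)
    clean <- matrix(0, nrow = nv, ncol = length(labs),
                    dimnames = list(NULL, masks$names[labs]))
    for (li in seq_along(labs)) clean[, li] <- roi_signal(truths[[masks$names[labs[li]]]])
    # background voxels share the average noise character of the regions
    bg_nsd <- mean(vapply(truths, `[[`, 0, "noise_sd"))
    bg_rho <- mean(vapply(truths, `[[`, 0, "ar1"))
    bg_dra <- mean(vapply(truths, `[[`, 0, "drift_amplitude"))
    for (v in seq_len(nvox)) {
      l <- lab_vec[v]
      truth <- if (l > 0L) truths[[masks$names[l]]] else NULL
      nsd <- if (is.null(truth)) bg_nsd else truth$noise_sd
      rho <- if (is.null(truth)) bg_rho else truth$ar1
      dra <- if (is.null(truth)) bg_dra else truth$drift_amplitude
      sig <- if (l > 0L) clean[, match(l, labs)] else 0
      ph <- stats::runif(2, 0, 2 * pi)
      drift <- dra * (cos(2 * pi * vol_t / 192 + ph[1]) +
                        cos(2 * pi * vol_t / 288 + ph[2]))
      flat[, v] <- 100 + sig + drift + ar1_noise(nv, nsd, rho)
    }
    dat[] <- t(flat)
    bold <- structure(list(data = dat, tr = spec$tr,
                           affine = diag(c(3, 3, 3, 1)),
                           run_id = sprintf("sub%03d_run%d", subject, run)),
                      class = "bold_run")
    motion <- sapply(1:6, function(p) {
      sdp <- if (p <= 3) motion_sd else motion_sd / 2
      w <- cumsum(stats::rnorm(nv + 4L, 0, sdp))
      w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
      w <- w[3:(nv + 2L)]
      w - w[1]
    })
    colnames(motion) <- c("x", "y", "z", "pitch", "roll", "yaw")
    list(run = bold, motion = motion, clean = clean)
  })
}

# linear "open" convolution truncated to the length of x
.conv_sample <- function(x, kern) {
  if (!any(x != 0)) return(numeric(length(x)))
  out <- stats::convolve(x, rev(as.numeric(kern)), type = "open")
  out[seq_along(x)]
}

#' Simulate the event tables of a whole cohort
#'
#' Draws trial sequences for every subject and run; imaging data, being
#' much heavier, is simulated per run via [simulate_run()] when needed.
#'
#' @param spec A [cohort_spec()].
#' @param model An [rt_model()].
#' @param ... Passed to [simulate_trials()].
#' @return List with `subjects` (data.frame: subject, group) and `events`
#'   (list indexed `[[subject]][[run]]` of event tables).
#' @export
simulate_cohort <- function(spec, model = default_rt_model(), ...) {
  n <- spec$n_control + spec$n_patient
  subjects <- data.frame(
    subject = sprintf("sub%03d", seq_len(n)),
    group = rep(c("control", "patient"), c(spec$n_control, spec$n_patient)),
    stringsAsFactors = FALSE)
  events <- lapply(seq_len(n), function(s) {
    lapply(seq_len(spec$runs_per_subject), function(r) {
      simulate_trials(spec, model, subjects$group[s], subject = s, run = r, ...)
    })
  })
  names(events) <- subjects$subject
  list(subjects = subjects, events = events)
}

#' Write a simulated run to disk
#'
#' NIfTI-1 for the 4-D data and ROI labels, BIDS-style `*_events.tsv` for
#' events, 6-column whitespace text for motion.
#'
#' @param sim Result of [simulate_run()].
#' @param events The run's [event_table()].
#' @param masks The [make_roi_masks()] result (written once as labels).
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_run <- function(sim, events, masks, dir, prefix = sim$run$run_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(bold = file.path(dir, paste0(prefix, "_bold.nii")),
         events = file.path(dir, paste0(prefix, "_events.tsv")),
         motion = file.path(dir, paste0(prefix, "_motion.txt")),
         masks = file.path(dir, "synthetic_roi_labels.nii"))
  img <- RNifti::asNifti(sim$run$data)
  RNifti::pixdim(img) <- c(3, 3, 3, sim$run$tr)
  RNifti::writeNifti(img, p["bold"])
  write_events_tsv(events, p["events"])
  write_motion(sim$motion, p["motion"])
  RNifti::writeNifti(RNifti::asNifti(masks$labels + 0), p["masks"])
  invisible(p)
}

#' Read a 4-D NIfTI run
#' @param path NIfTI file.
#' @param tr Repetition time in seconds (taken from the header pixdim if
#'   absent).
#' @param run_id Identifier to attach.
#' @return A `bold_run`.
#' @export
read_bold_run <- function(path, tr = NULL, run_id = basename(path)) {
  img <- RNifti::readNifti(path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  structure(list(data = unclass(img)[, , , , drop = FALSE], tr = tr,
                 affine = RNifti::xform(img), run_id = run_id),
            class = "bold_run")
}

#' Build a cohort specification and RT model from a YAML config
#'
#' The file mirrors [cohort_spec()] and [rt_model()]: top-level keys
#' `n_control, n_patient, runs_per_subject, run_duration, tr, seed`, and an
#' `rt_model` block with `mean`, `sd`, `accuracy` each holding `control`
#' and `patient` 3-vectors (congruent, easy, hard).
#'
#' @param path YAML file path.
#' @return List with elements `spec` and `model`.
#' @export
cohort_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  cfg <- yaml::read_yaml(path)
  spec <- cohort_spec(cfg$n_control, cfg$n_patient,
                      cfg$runs_per_subject %||% 6,
                      cfg$run_duration %||% 300,
                      cfg$tr %||% 1.92, cfg$seed %||% 1L)
  model <- if (is.null(cfg$rt_model)) default_rt_model() else {
    rt_model(rbind(control = cfg$rt_model$mean$control,
                   patient = cfg$rt_model$mean$patient),
             rbind(control = cfg$rt_model$sd$control,
                   patient = cfg$rt_model$sd$patient),
             rbind(control = cfg$rt_model$accuracy$control,
                   patient = cfg$rt_model$accuracy$patient))
  }
  list(spec = spec, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
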
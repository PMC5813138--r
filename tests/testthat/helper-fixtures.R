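# shared small fixtures, all generated in code

tiny_spec <- function(seed = 7, runs = 1, n1 = 2, n2 = 2) {
  cohort_spec(n1, n2, runs_per_subject = runs, seed = seed)
}

single_roi_masks <- function() {
  make_roi_masks(c(8, 8, 4), n_rois = 1, names = "roi1")
}

# strip cue rows so target regressors are free of cue-target collinearity
targets_only <- function(ev) {
  out <- ev[ev$trial_type != "cue", ]
  class(out) <- c("event_table", "data.frame")
  out
}

impulse_truth <- function(shift, amp = 2, noise = 0, ar1 = 0, drift = 0) {
  roi_truth("roi1", "impulse_positive", amplitude = amp,
            onset_shift = shift, noise_sd = noise, ar1 = ar1,
            drift_amplitude = drift, cue_amplitude = 0)
}

# one full noiseless single-ROI run -> subject fit, reused across tests
fit_single_roi <- function(shift = 0, amp = 2, noise = 0, ar1 = 0,
                           drift = 0, seed = 7, with_cues = FALSE,
                           group = "control") {
  spec <- tiny_spec(seed = seed)
  masks <- single_roi_masks()
  ev <- simulate_trials(spec, group = group, subject = 1, run = 1)
  if (!with_cues) ev <- targets_only(ev)
  truth <- impulse_truth(shift, amp, noise, ar1, drift)
  sim <- simulate_run(spec, ev, list(roi1 = truth), masks, group, 1, 1)
  des <- build_design(ev, n_volumes(spec), spec$tr)
  list(spec = spec, masks = masks, events = ev, sim = sim, design = des,
       fit = fit_glm(sim$run, des))
}

roi_voxels <- function(masks, label = 1) which(as.integer(masks$labels) == label)
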
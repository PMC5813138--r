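test_that("run geometry: 300 s at TR 1.92 s gives 156 volumes", {
  spec <- cohort_spec(2, 2)
  expect_identical(n_volumes(spec), 156L)
  expect_error(cohort_spec(2, 2, run_duration = 10, tr = 1.92),
               "at least 10 volumes")
  expect_error(cohort_spec(1, 2), "n_control")
})

test_that("trial sequences are ordered, in-bounds and deterministic", {
  spec <- tiny_spec(seed = 11)
  ev1 <- simulate_trials(spec, group = "patient", subject = 1, run = 1)
  ev2 <- simulate_trials(spec, group = "patient", subject = 1, run = 1)
  expect_identical(ev1, ev2)
  ev3 <- simulate_trials(spec, group = "patient", subject = 2, run = 1)
  expect_false(identical(ev1$onset, ev3$onset))

  expect_true(all(diff(ev1$onset) > 0))
  expect_true(all(ev1$onset >= 0 & ev1$onset < 300))
  tgt <- ev1$trial_type %in% event_conditions()
  expect_true(all(ev1$onset[tgt] + ev1$response_time[tgt] / 1000 < 300))
  # every target follows its cue within the jittered gap range
  gaps <- diff(ev1$onset)[seq(1, sum(tgt) * 2 - 1, by = 2)]
  expect_true(all(gaps >= 0.5 & gaps <= 1.5))
})

test_that("generated RTs recover the configured group-by-condition means", {
  spec <- cohort_spec(2, 2, runs_per_subject = 1, seed = 3)
  model <- default_rt_model()
  # pool many independent runs to get a large sample per condition
  evs <- lapply(1:450, function(r)
    simulate_trials(spec, model, "patient", subject = 1, run = r))
  ev <- do.call(rbind, lapply(evs, as.data.frame))
  for (cnd in event_conditions()) {
    x <- ev$response_time[ev$trial_type == cnd]
    expect_gt(length(x), 3000)
    se <- model$rt_sd["patient", cnd] / sqrt(length(x))
    expect_lt(abs(mean(x) - model$rt_mean["patient", cnd]), 3 * se)
    # SD should also be close (lognormal matched to mean/SD)
    expect_lt(abs(sd(x) - model$rt_sd["patient", cnd]),
              0.1 * model$rt_sd["patient", cnd])
  }
})

test_that("degenerate accuracy and too-short runs behave as specified", {
  spec <- tiny_spec(seed = 5)
  perfect <- rt_model(default_rt_model()$rt_mean, default_rt_model()$rt_sd,
                      matrix(1, 2, 3))
  ev <- simulate_trials(spec, perfect, "control", 1, 1)
  tgt <- ev$trial_type %in% event_conditions()
  expect_true(all(ev$accuracy[tgt] == 1))

  short <- cohort_spec(2, 2, run_duration = 20, seed = 1)
  expect_error(simulate_trials(short, group = "patient", subject = 1, run = 1,
                               iti_range = c(30, 40)),
               "too short")
})

test_that("ROI masks are disjoint labelled blocks of at least 8 voxels", {
  m <- make_roi_masks()
  expect_length(m$names, 9)
  expect_identical(m$names, roi_names())
  counts <- table(m$labels[m$labels > 0])
  expect_length(counts, 9)          # labels pairwise disjoint by coding
  expect_true(all(counts >= 8))
  m1 <- make_roi_masks(c(8, 8, 4), n_rois = 1)
  expect_identical(sum(m1$labels == 1L), 27L)
  expect_error(make_roi_masks(c(4, 4, 2), n_rois = 9), "too small")
})

test_that("noiseless forward model reproduces the sampled canonical HRF", {
  spec <- tiny_spec()
  masks <- single_roi_masks()
  ev <- event_table(onset = 20, duration = 0, trial_type = "congruent",
                    response_time = 800, accuracy = 1, run_duration = 300)
  amp <- 2
  sim <- simulate_run(spec, ev, list(roi1 = impulse_truth(0, amp)), masks,
                      "control", 1, 1)
  y <- apply(sim$run$data, 4, function(v) mean(v[roi_voxels(masks)])) - 100
  # oracle: canonical kernel evaluated at volume times past the onset
  # (the generator snaps onsets to its oversampled grid)
  vol_t <- (seq_len(n_volumes(spec)) - 1) * spec$tr
  dt <- spec$tr / 16
  on_snap <- round(20 / dt) * dt
  k <- canonical_hrf(dt)
  expected <- amp * approx(attr(k, "time") + on_snap, as.numeric(k),
                           xout = vol_t, yleft = 0, yright = 0)$y
  expect_lt(max(abs(y - expected)), 1e-8)
  expect_equal(dim(sim$run$data)[4], 156)
})

test_that("an onset shift moves the cross-correlation peak by that shift", {
  spec <- tiny_spec()
  masks <- single_roi_masks()
  ev <- event_table(onset = 20, duration = 0, trial_type = "congruent",
                    response_time = 800, accuracy = 1, run_duration = 300)
  vol_t <- (seq_len(n_volumes(spec)) - 1) * spec$tr
  k <- canonical_hrf(spec$tr / 16)
  ref <- approx(attr(k, "time") + 20, as.numeric(k), xout = vol_t,
                yleft = 0, yright = 0)$y
  for (shift in c(-0.5, 0.5)) {
    sim <- simulate_run(spec, ev, list(roi1 = impulse_truth(shift)), masks,
                        "control", 1, 1)
    y <- apply(sim$run$data, 4, function(v) mean(v[roi_voxels(masks)])) - 100
    lag <- oracle_xcorr_lag(y, ref, spec$tr)
    expect_lt(abs(lag - shift), 0.13)   # one oversampled-grid step
  }
})

test_that("identical seeds give bit-identical voxel data; shifts out of range refuse", {
  spec <- tiny_spec(seed = 21)
  masks <- single_roi_masks()
  ev <- targets_only(simulate_trials(spec, group = "control", subject = 1, run = 1))
  s1 <- simulate_run(spec, ev, list(roi1 = impulse_truth(0, noise = 1)), masks,
                     "control", 1, 1)
  s2 <- simulate_run(spec, ev, list(roi1 = impulse_truth(0, noise = 1)), masks,
                     "control", 1, 1)
  expect_identical(s1$run$data, s2$run$data)
  expect_identical(s1$motion, s2$motion)

  expect_error(roi_truth("roi1", "impulse_positive", 1, onset_shift = 1.9),
               "1.78")
  expect_error(roi_truth("roi1", "boxcar_negative", 0.5), "negative")
})

test_that("DMN boxcar deactivation magnitude grows with trial duration", {
  spec <- tiny_spec()
  masks <- single_roi_masks()
  dmn <- roi_truth("roi1", "boxcar_negative", -2, 0, noise_sd = 0, ar1 = 0,
                   drift_amplitude = 0)
  mk <- function(rt) event_table(onset = 20, duration = 0,
                                 trial_type = "congruent",
                                 response_time = rt, accuracy = 1,
                                 run_duration = 300)
  dip <- sapply(c(700, 1800), function(rt) {
    sim <- simulate_run(spec, mk(rt), list(roi1 = dmn), masks, "control", 1, 1)
    min(apply(sim$run$data, 4, function(v) mean(v[roi_voxels(masks)])) - 100)
  })
  expect_lt(dip[1], 0)
  expect_lt(dip[2], dip[1])   # longer RT -> deeper deactivation
})

test_that("round-trip through disk preserves events, motion and volumes", {
  spec <- tiny_spec(seed = 31)
  masks <- single_roi_masks()
  ev <- simulate_trials(spec, group = "control", subject = 1, run = 1)
  sim <- simulate_run(spec, ev, list(roi1 = impulse_truth(0, noise = 0.5)),
                      masks, "control", 1, 1)
  d <- withr::local_tempdir()
  paths <- write_run(sim, ev, masks, d)
  ev2 <- read_events_tsv(paths["events"])
  expect_equal(as.data.frame(ev2), as.data.frame(ev), tolerance = 1e-6)
  m2 <- read_motion(paths["motion"])
  expect_equal(unname(m2), unname(sim$motion), tolerance = 1e-6)
  run2 <- read_bold_run(paths["bold"])
  expect_equal(dim(run2$data), dim(sim$run$data))
  expect_equal(run2$tr, spec$tr, tolerance = 1e-6)
  expect_equal(max(abs(run2$data - sim$run$data)), 0, tolerance = 1e-4)
})
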
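# Generator: configuration contracts, determinism, event bookkeeping, and
# ground-truth behaviour of the injected components.

test_that("invalid configuration fields raise errors naming the field", {
  expect_error(synth_config(n_tms_trials = 0), "n_tms_trials")
  expect_error(synth_config(isi = 1.0001, fs_raw = 500), "isi")
  expect_error(synth_config(fs_raw = 100), "fs_raw")
  expect_error(synth_config(contact_falloff = 1.5), "contact_falloff")
  expect_error(region_profile("x", hfa_suppression = 2), "hfa_suppression")
  expect_error(region_profile("x", suppression_window = c(0.5, 0.2)),
               "suppression_window")
})

test_that("the event table carries the configured trial counts per condition", {
  cfg <- synth_config(n_subjects = 1, contacts_per_region = 2,
                      region_profiles = list(region_profile("r")),
                      n_tms_trials = 150, n_sham_trials = 300,
                      fs_raw = 500, rng_seed = 3)
  ds <- generate_dataset(cfg)
  expect_identical(sum(ds$events$condition == "tms"), 150L)
  expect_identical(sum(ds$events$condition == "sham"), 300L)
  expect_silent(validate_events(ds$events))
  expect_true(all(diff(ds$events$onset_s) >= 1.9))
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- synth_config(n_subjects = 2, contacts_per_region = 2,
                      n_tms_trials = 5, n_sham_trials = 5,
                      fs_raw = 500, rng_seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$recordings[[1]]$data, d2$recordings[[1]]$data)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$ground_truth, d2$ground_truth)
})

test_that("with all effects silenced, TMS and sham are the same process", {
  # mean contact t-statistic ~ 0 across >= 50 contacts; two-contact shafts
  # keep the contact statistics independent across shafts
  prof <- lapply(sprintf("n%d", 1:10), region_profile, sham_click_amp = 0)
  cfg <- synth_config(n_subjects = 10, contacts_per_region = 2,
                      region_profiles = prof,
                      n_tms_trials = 12, n_sham_trials = 12,
                      artifact_amplitude = 0, line_noise_amplitude = 0,
                      fs_raw = 500, rng_seed = 17)
  ds <- generate_dataset(cfg)
  ts <- c()
  for (s in names(ds$recordings)) {
    ch <- ds$channels[ds$channels$subject == s, ]
    ev <- ds$events[ds$events$subject == s, ]
    rr <- rereference(ds$recordings[[s]], ch)
    ep <- epoch_recording(rr$recording, ev)
    bp <- band_power(ep, band_spec("theta"))
    ts <- c(ts, rowMeans(suppressWarnings(power_tstats(bp))))
  }
  expect_gte(length(ts), 50)
  expect_lt(abs(mean(ts)), 0.2)
})

test_that("induced-only trials have random phase but elevated theta power", {
  prof <- region_profile("ind", induced_amp = 12, induced_freq = 6,
                         sham_click_amp = 0)
  cfg <- synth_config(n_subjects = 1, contacts_per_region = 2,
                      region_profiles = list(prof),
                      n_tms_trials = 120, n_sham_trials = 120,
                      artifact_amplitude = 0, line_noise_amplitude = 0,
                      fs_raw = 500, rng_seed = 21)
  ds <- generate_dataset(cfg)
  gt <- ds$ground_truth[["sub-01"]]$regions[["ind"]]
  phases <- gt$induced_phase[gt$condition == "tms"]
  expect_gte(length(phases), 100)
  # resultant-vector oracle on the stored ground-truth phases
  expect_lt(phase_locking_value(phases), 0.4)
  # trial-averaged theta power exceeds sham
  rr <- rereference(ds$recordings[[1]], ds$channels)
  ep <- epoch_recording(rr$recording, ds$events)
  wp <- windowed_power(ep, band_spec("theta"))
  tms_p <- mean(wp$values[ep$condition == "tms", 1, 3])   # 0.25-0.75 s
  sham_p <- mean(wp$values[ep$condition == "sham", 1, 3])
  expect_gt(tms_p, sham_p)
})

test_that("evoked-only trials phase-lock strongly at the injected frequency", {
  prof <- region_profile("ev", evoked_amp = 10, evoked_freq = 5,
                         evoked_decay = 0.3, sham_click_amp = 0)
  set.seed(31)
  ep <- make_epochs(function(i)
    synth_trial(prof, "tms", fs = 500), n_trials = 100)
  ipl <- inter_trial_phase_locking(ep, freqs = 5)
  early <- ipl$times >= 0 & ipl$times < 0.5
  expect_gt(max(ipl$ipl[1, 1, early]), 0.7)
})

test_that("full suppression forces 70-110 Hz power below baseline in every trial", {
  prof <- region_profile("sup", hfa_suppression = 1,
                         suppression_window = c(0.25, 0.75),
                         sham_click_amp = 0)
  set.seed(33)
  b <- band_spec("custom", f_lo = 70, f_hi = 110, window_width = 0.5)
  worse <- replicate(20, {
    x <- synth_trial(prof, "tms", fs = 500)
    fs <- 500
    win <- x[(round(0.75 * fs) + 1):(round(1.25 * fs))]       # 0.25-0.75 s
    base <- x[1:round(0.45 * fs)]                             # baseline
    multitaper_band_power(win, fs, b) <
      multitaper_band_power(base, fs, b, enforce_width = FALSE)
  })
  expect_true(all(worse))
})

test_that("sham trials carry only the small click component", {
  prof <- region_profile("ev", evoked_amp = 10, evoked_freq = 5,
                         induced_amp = 8, sham_click_amp = 1)
  set.seed(35)
  x <- synth_trial(prof, "sham", fs = 500)
  expect_true(is.na(attr(x, "induced_phase")))
  # average of many sham trials shows the deterministic click, far smaller
  # than the evoked amplitude
  avg <- rowMeans(replicate(60, as.numeric(synth_trial(prof, "sham", fs = 500))))
  post <- avg[251:375]
  expect_lt(max(abs(post)), 2)       # click amp 1 << evoked amp 10
  expect_gt(max(abs(post)), 0.3)     # but present
})
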
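# Shared fixtures, built in code. Heavyweight simulated objects are
# memoized for the session so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# epoch_set from a per-trial generator function gen(i) -> waveform
make_epochs <- function(gen, n_trials = 30, fs = 500, t0 = -0.5,
                        duration = 2.5,
                        condition = rep("tms", n_trials)) {
  n <- round(duration * fs)
  data <- array(NA_real_, c(n_trials, 1, n))
  for (i in seq_len(n_trials)) data[i, 1, ] <- gen(i)
  structure(list(data = data, fs = fs, t0 = t0, duration = duration,
                 condition = condition, target = NULL, subject = "sub-01",
                 channel_names = "c1",
                 times = t0 + (seq_len(n) - 1L) / fs),
            class = "epoch_set")
}

# channel table row builder
ch_row <- function(name, subject = "sub-01", montage = "depth", shaft = "A",
                   idx = 1, label = "ctx", roi = "ctx", status = "good",
                   reason = "none") {
  data.frame(name = name, subject = subject, montage_type = montage,
             shaft = shaft, contact_index = idx, anatomical_label = label,
             roi = roi, status = status, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

# One all-null pipeline repetition: 5 subjects, one silent region, theta
# band; returns the fraction of FDR-significant windows.
null_rep_fraction <- function(seed) {
  prof <- region_profile("null_region", sham_click_amp = 0)
  cfg <- synth_config(n_subjects = 5, contacts_per_region = 3,
                      region_profiles = list(prof),
                      n_tms_trials = 15, n_sham_trials = 15,
                      artifact_amplitude = 0, line_noise_amplitude = 0,
                      fs_raw = 500, rng_seed = seed)
  ds <- generate_dataset(cfg)
  rows <- list()
  for (s in names(ds$recordings)) {
    ch <- ds$channels[ds$channels$subject == s, ]
    ev <- ds$events[ds$events$subject == s, ]
    rr <- rereference(ds$recordings[[s]], ch)
    ep <- epoch_recording(rr$recording, ev)
    bp <- band_power(ep, band_spec("theta"))
    tm <- suppressWarnings(power_tstats(bp))
    for (w in seq_along(bp$window_starts))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, roi = "null_region",
        window_start = bp$window_starts[w], t = tm[, w])
  }
  g <- group_effects(do.call(rbind, rows))
  mean(g$significant)
}

# 3894-contact channel table carrying the reference exclusion counts
exclusion_fixture <- function() {
  n <- 3894
  reason <- rep("none", n)
  reason[1:412] <- "seizure"
  reason[413:(412 + 835)] <- "saturation"
  reason[(412 + 835 + 1):(412 + 835 + 67)] <- "noise"
  ch_row(sprintf("c%04d", seq_len(n)), subject = "sub-01", idx = seq_len(n),
         status = ifelse(reason == "none", "good", "excluded"),
         reason = reason)
}

# Full-scale simulated study shared by the end-to-end acceptance checks
acceptance_pipeline <- function() {
  memo("acceptance_pipeline", function() {
    run_pipeline(default_config(seed = 123))
  })
}

# Brute-force Benjamini-Hochberg step-up oracle (independent of p.adjust):
# enumerates the largest k with p_(k) <= k/m * alpha and computes q-values
# by the step-up minimum rule.
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- (seq_len(m) / m) * alpha
  k <- max(c(0L, which(ps <= thresh)))
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  q_sorted <- numeric(m)
  for (i in seq_len(m)) q_sorted[i] <- min(ps[i:m] * m / (i:m))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(reject = reject, q = q)
}

# unit-SD 1/f^2 background trace (the generator's background process)
shaped_bg_for_tests <- function(n, fs)
  stimspect:::shaped_background(n, fs, exponent = 2)
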
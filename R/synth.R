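# Synthetic multi-subject TMS-iEEG generator. Every downstream stage of the
# pipeline is validated against recordings produced here, where the injected
# evoked/induced/suppression effects are known exactly.
#
# Signal model per contact: 1/f^a shaped Gaussian background (band-passed to
# emulate the acquisition filter), common 60 Hz line noise, and per-pulse
# components added at each event: a biphasic stimulation artifact, a
# phase-locked damped low-frequency evoked transient, a phase-randomized
# induced oscillatory burst, and multiplicative suppression of the 70-110 Hz
# background after the pulse. Regional effect amplitude falls off
# geometrically along the depth shaft (dipole-like), so bipolar derivations
# retain a consistent-sign effect.

#' Regional effect profile for the synthetic generator
#'
#' @param label anatomical region name
#' @param evoked_amp amplitude of the phase-locked damped evoked oscillatory
#'   component, in units of the background SD (default 0)
#' @param evoked_freq evoked carrier frequency, Hz
#' @param evoked_decay evoked exponential decay time constant, seconds
#'   (shared by the oscillatory and broadband evoked components)
#' @param evoked_broadband_amp amplitude of the phase-locked broadband
#'   evoked transient (SD units): a frozen 1/f-shaped waveform, identical
#'   across trials, damped with `evoked_decay` — the spectrally smooth bulk
#'   of an evoked potential, which elevates band power and phase locking
#'   without creating a discrete spectral peak
#' @param induced_amp amplitude of the phase-jittered induced burst (SD units)
#' @param induced_freq induced burst carrier frequency, Hz
#' @param induced_latency earliest burst onset relative to the pulse, seconds
#' @param induced_latency_jitter burst latency jitter, uniform on
#'   `[0, induced_latency_jitter]` seconds
#' @param hfa_suppression fraction in `[0, 1]` of the 70-110 Hz background
#'   amplitude removed in `suppression_window`
#' @param suppression_window `(start, end)` of the suppression interval,
#'   seconds after the pulse
#' @param sham_click_amp amplitude of the small fixed-latency auditory-click
#'   evoked component added to sham trials (SD units)
#' @return a `region_profile` object
#' @export
region_profile <- function(label,
                           evoked_amp = 0, evoked_freq = 3, evoked_decay = 0.15,
                           evoked_broadband_amp = 0,
                           induced_amp = 0, induced_freq = 6,
                           induced_latency = 0.1, induced_latency_jitter = 0.2,
                           hfa_suppression = 0, suppression_window = c(0.25, 0.75),
                           sham_click_amp = 2) {
  if (!is.character(label) || length(label) != 1L)
    stop_param("label", "must be a single string")
  check_scalar(evoked_amp, "evoked_amp", lower = 0)
  check_scalar(evoked_freq, "evoked_freq", lower = 1e-6)
  check_scalar(evoked_decay, "evoked_decay", lower = 1e-6)
  check_scalar(evoked_broadband_amp, "evoked_broadband_amp", lower = 0)
  check_scalar(induced_amp, "induced_amp", lower = 0)
  check_scalar(induced_freq, "induced_freq", lower = 1e-6)
  check_scalar(induced_latency, "induced_latency", lower = 0)
  check_scalar(induced_latency_jitter, "induced_latency_jitter", lower = 0)
  check_scalar(hfa_suppression, "hfa_suppression", lower = 0, upper = 1)
  check_scalar(sham_click_amp, "sham_click_amp", lower = 0)
  if (length(suppression_window) != 2L || suppression_window[1] >= suppression_window[2])
    stop_param("suppression_window", "must be (start, end) with start < end")
  structure(list(label = label, evoked_amp = evoked_amp,
                 evoked_freq = evoked_freq, evoked_decay = evoked_decay,
                 evoked_broadband_amp = evoked_broadband_amp,
                 induced_amp = induced_amp, induced_freq = induced_freq,
                 induced_latency = induced_latency,
                 induced_latency_jitter = induced_latency_jitter,
                 hfa_suppression = hfa_suppression,
                 suppression_window = as.numeric(suppression_window),
                 sham_click_amp = sham_click_amp),
            class = "region_profile")
}

#' Default region profiles: evoked, induced and suppression archetypes
#'
#' Three regions capturing the response phenomenology the pipeline is built
#' to dissociate: a heavily damped phase-locked low-frequency transient
#' (broadband evoked potential), a phase-randomized narrowband theta burst
#' (induced oscillation), and post-pulse suppression of high-frequency
#' activity.
#' @return list of three `region_profile` objects
#' @export
default_region_profiles <- function() {
  list(
    region_profile("evoked_theta", evoked_amp = 4, evoked_freq = 5,
                   evoked_decay = 0.3, evoked_broadband_amp = 20),
    region_profile("induced_theta", induced_amp = 12, induced_freq = 6,
                   induced_latency = 0.1, induced_latency_jitter = 0.2),
    region_profile("hfa_suppression", hfa_suppression = 0.8,
                   suppression_window = c(0.25, 0.75))
  )
}

#' Synthetic-dataset configuration
#'
#' @param n_subjects number of simulated subjects
#' @param contacts_per_region depth contacts per region shaft (bipolar
#'   re-referencing yields one fewer derived channel)
#' @param region_profiles list of [region_profile()] objects
#' @param fs_raw acquisition sampling rate, Hz
#' @param n_tms_trials,n_sham_trials pulse counts per condition
#' @param isi inter-stimulation interval, seconds
#' @param artifact_duration stimulation-artifact duration, seconds
#' @param artifact_amplitude artifact amplitude in background-SD units
#' @param line_noise_amplitude 60 Hz line amplitude (SD units)
#' @param background_exponent 1/f^a exponent of the background spectrum
#' @param subject_gain_sd SD of the per-subject log-normal gain
#' @param contact_falloff per-contact geometric amplitude falloff of regional
#'   effects along the shaft
#' @param amplitude_drift total fractional change of effect amplitudes from
#'   the first to the last active trial (0 = stationary session)
#' @param target stimulation target label for the event table
#' @param rng_seed integer seed; identical seeds give bit-identical datasets
#' @return a `synth_config` object
#' @export
synth_config <- function(n_subjects = 6, contacts_per_region = 5,
                         region_profiles = default_region_profiles(),
                         fs_raw = 8000, n_tms_trials = 100, n_sham_trials = 100,
                         isi = 2.0, artifact_duration = 0.015,
                         artifact_amplitude = 50, line_noise_amplitude = 0.5,
                         background_exponent = 2.0, subject_gain_sd = 0.2,
                         contact_falloff = 0.5, amplitude_drift = 0,
                         target = "dlpfc", rng_seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 1)
  check_scalar(contacts_per_region, "contacts_per_region", lower = 2)
  check_scalar(fs_raw, "fs_raw", lower = 1)
  check_scalar(n_tms_trials, "n_tms_trials", lower = 1)
  check_scalar(n_sham_trials, "n_sham_trials", lower = 1)
  check_scalar(isi, "isi", lower = 0.1)
  check_scalar(artifact_duration, "artifact_duration", lower = 0)
  check_scalar(artifact_amplitude, "artifact_amplitude", lower = 0)
  check_scalar(line_noise_amplitude, "line_noise_amplitude", lower = 0)
  check_scalar(background_exponent, "background_exponent", lower = 0)
  check_scalar(subject_gain_sd, "subject_gain_sd", lower = 0)
  check_scalar(contact_falloff, "contact_falloff", lower = 0, upper = 1)
  check_scalar(amplitude_drift, "amplitude_drift")
  if (!target %in% c("dlpfc", "parietal"))
    stop_param("target", "must be 'dlpfc' or 'parietal'")
  if (!is.list(region_profiles) || !length(region_profiles) ||
      !all(vapply(region_profiles, inherits, logical(1), "region_profile")))
    stop_param("region_profiles", "must be a non-empty list of region_profile objects")
  if (abs(isi * fs_raw - round(isi * fs_raw)) > 1e-9)
    stop_param("isi", "isi * fs_raw must be an integer number of samples")
  fmax <- max(vapply(region_profiles, function(p)
    max(p$evoked_freq, p$induced_freq, 110), numeric(1)))
  if (fs_raw <= 2 * fmax)
    stop_param("fs_raw", sprintf("must exceed twice the highest injected frequency (%g Hz)", fmax))
  structure(list(n_subjects = as.integer(n_subjects),
                 contacts_per_region = as.integer(contacts_per_region),
                 region_profiles = region_profiles, fs_raw = fs_raw,
                 n_tms_trials = as.integer(n_tms_trials),
                 n_sham_trials = as.integer(n_sham_trials), isi = isi,
                 artifact_duration = artifact_duration,
                 artifact_amplitude = artifact_amplitude,
                 line_noise_amplitude = line_noise_amplitude,
                 background_exponent = background_exponent,
                 subject_gain_sd = subject_gain_sd,
                 contact_falloff = contact_falloff,
                 amplitude_drift = amplitude_drift,
                 target = target, rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# 1/f^a shaped Gaussian background, spectrally band-passed (raised-cosine
# edges) to emulate the acquisition band-pass, normalized to unit SD.
# `deterministic_spectrum = TRUE` keeps the amplitude spectrum exactly at the
# target shape (random phases only) — used for the frozen broadband evoked
# waveform, whose per-realization spectral ripple would otherwise imprint
# consistent pseudo-peaks on every trial.
shaped_background <- function(n, fs, exponent, f_lo = 0.7, f_hi = 800,
                              deterministic_spectrum = FALSE) {
  f_hi <- min(f_hi, 0.45 * fs)
  X <- if (deterministic_spectrum) {
    ph <- stats::runif(n, 0, 2 * pi)
    # hermitian phases so the inverse transform is real
    half <- seq(2, ceiling(n / 2))
    ph[n + 2 - half] <- -ph[half]
    ph[1] <- 0
    if (n %% 2 == 0) ph[n / 2 + 1] <- 0
    exp(1i * ph)
  } else stats::fft(stats::rnorm(n))
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  shape <- ifelse(af > 0, af^(-exponent / 2), 0)
  # smooth band edges (half-cosine over 0.3 octave-ish widths)
  lo_w <- 0.5 * f_lo
  hi_w <- 0.1 * f_hi
  shape <- shape * pmin(1, pmax(0, (af - (f_lo - lo_w)) / (2 * lo_w)))
  shape <- shape * pmin(1, pmax(0, ((f_hi + hi_w) - af) / (2 * hi_w)))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# FFT brick-wall band-pass used for the suppression component
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  X[abs(f) < f_lo | abs(f) > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Effect waveforms, sampled on t seconds relative to pulse onset (t >= 0)
evoked_waveform <- function(t, amp, freq, decay) {
  amp * exp(-t / decay) * cos(2 * pi * freq * t)
}

click_waveform <- function(t, amp) {
  # small auditory-evoked response to the coil click: brief damped low-theta
  # transient, present in sham (and negligible next to active-TMS effects)
  amp * exp(-t / 0.08) * cos(2 * pi * 5 * t)
}

induced_waveform <- function(t, amp, freq, phase, latency, n_cycles = 3) {
  dur <- n_cycles / freq
  u <- t - latency
  env <- ifelse(u >= 0 & u < dur, 0.5 * (1 - cos(2 * pi * u / dur)), 0)
  amp * env * cos(2 * pi * freq * u + phase)
}

artifact_waveform <- function(t, amp, duration) {
  # biphasic transient spanning [-duration/2, duration/2] around the pulse
  u <- t + duration / 2
  ifelse(u >= 0 & u < duration, amp * sin(2 * pi * u / duration), 0)
}

#' Synthesize a single standalone trial
#'
#' Generates one trial (background plus condition-appropriate components) for
#' a region profile, using the caller's RNG state. Active trials carry the
#' artifact, the phase-locked evoked transient, the phase-randomized induced
#' burst and HFA suppression; sham trials carry only a small fixed-latency
#' click component.
#'
#' @param profile a [region_profile()]
#' @param condition `"tms"` or `"sham"`
#' @param fs sampling rate, Hz
#' @param t0 trial start relative to the pulse, seconds (default -0.5)
#' @param duration trial length, seconds (default 2.5)
#' @param background_exponent 1/f exponent of the background
#' @param artifact_amplitude,artifact_duration artifact parameters; set the
#'   amplitude to 0 for artifact-free trials
#' @param broadband_shape frozen unit-SD waveform used for the broadband
#'   evoked component (length >= the post-stimulation sample count). Pass
#'   the same vector for every trial of a simulated contact so the
#'   component is phase-locked; when `NULL` a fresh one is drawn
#' @return numeric waveform of `round(duration * fs)` samples with attributes
#'   `induced_phase` and `induced_latency` (ground truth; `NA` for sham)
#' @export
synth_trial <- function(profile, condition = c("tms", "sham"), fs,
                        t0 = -0.5, duration = 2.5, background_exponent = 2,
                        artifact_amplitude = 0, artifact_duration = 0.015,
                        broadband_shape = NULL) {
  condition <- match.arg(condition)
  n <- round(duration * fs)
  x <- shaped_background(n, fs, background_exponent)
  t <- t0 + (seq_len(n) - 1L) / fs
  post <- t >= 0
  phase <- NA_real_
  latency <- NA_real_
  if (condition == "tms") {
    if (profile$evoked_amp > 0)
      x[post] <- x[post] + evoked_waveform(t[post], profile$evoked_amp,
                                           profile$evoked_freq, profile$evoked_decay)
    if (profile$evoked_broadband_amp > 0) {
      np <- sum(post)
      if (is.null(broadband_shape))
        broadband_shape <- shaped_background(max(np, round(fs)), fs,
                                             background_exponent,
                                             deterministic_spectrum = TRUE)
      x[post] <- x[post] + profile$evoked_broadband_amp *
        exp(-t[post] / profile$evoked_decay) * broadband_shape[seq_len(np)]
    }
    if (profile$induced_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      latency <- profile$induced_latency +
        stats::runif(1, 0, profile$induced_latency_jitter)
      x[post] <- x[post] + induced_waveform(t[post], profile$induced_amp,
                                            profile$induced_freq, phase, latency)
    }
    if (profile$hfa_suppression > 0) {
      band <- fft_bandpass(x, fs, 70, 110)
      w <- t >= profile$suppression_window[1] & t < profile$suppression_window[2]
      x[w] <- x[w] - profile$hfa_suppression * band[w]
    }
    if (artifact_amplitude > 0)
      x <- x + artifact_waveform(t, artifact_amplitude, artifact_duration)
  } else {
    if (profile$sham_click_amp > 0)
      x[post] <- x[post] + click_waveform(t[post], profile$sham_click_amp)
  }
  attr(x, "induced_phase") <- phase
  attr(x, "induced_latency") <- latency
  x
}

#' Generate a complete multi-subject synthetic dataset
#'
#' Produces one continuous recording per subject containing a randomized
#' interleaving of active and sham pulses at the configured
#' inter-stimulation interval, together with the channel table, event table
#' and a ground-truth record of every injected trial parameter. Identical
#' seeds give bit-identical output.
#'
#' @param config a [synth_config()]
#' @return list with `recordings` (named list of `continuous_recording`),
#'   `channels` (channel table for all subjects), `events` (event table with
#'   `subject`, `session`, `onset_s`, `condition`, `target`), `ground_truth`
#'   (per subject: per-event induced phase/latency per region, plus the
#'   subject gain), and `config`
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_param("config", "must be a synth_config object")
  with_seed(config$rng_seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  fs <- config$fs_raw
  n_ev <- config$n_tms_trials + config$n_sham_trials
  lead_in <- 5
  total_dur <- lead_in + n_ev * config$isi + 3
  n <- round(total_dur * fs)
  profiles <- config$region_profiles
  m <- config$contacts_per_region
  recordings <- list()
  channels_all <- list()
  events_all <- list()
  ground_truth <- list()

  for (s in seq_len(config$n_subjects)) {
    subj <- sprintf("sub-%02d", s)
    gain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))
    cond <- sample(rep(c("tms", "sham"),
                       c(config$n_tms_trials, config$n_sham_trials)))
    onsets <- lead_in + (seq_len(n_ev) - 1L) * config$isi
    events <- data.frame(subject = subj, session = "ses-01",
                         onset_s = onsets, condition = cond,
                         target = config$target, stringsAsFactors = FALSE)
    tms_rank <- cumsum(cond == "tms")      # position among active trials
    drift_gain <- rep(1, n_ev)
    if (config$amplitude_drift != 0 && config$n_tms_trials > 1) {
      frac <- (tms_rank - 1) / (config$n_tms_trials - 1)
      drift_gain <- 1 + config$amplitude_drift * pmax(0, pmin(1, frac))
    }

    n_ch <- length(profiles) * m
    data <- matrix(0, n_ch, n)
    ch_rows <- vector("list", n_ch)
    gt_regions <- list()
    line <- if (config$line_noise_amplitude > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      config$line_noise_amplitude * sin(2 * pi * 60 * (seq_len(n) - 1L) / fs + ph)
    } else 0

    for (r in seq_along(profiles)) {
      p <- profiles[[r]]
      # per-event regional parameters (shared across the shaft)
      is_tms <- cond == "tms"
      ind_phase <- rep(NA_real_, n_ev)
      ind_lat <- rep(NA_real_, n_ev)
      if (p$induced_amp > 0) {
        ind_phase[is_tms] <- stats::runif(sum(is_tms), 0, 2 * pi)
        ind_lat[is_tms] <- p$induced_latency +
          stats::runif(sum(is_tms), 0, p$induced_latency_jitter)
      }
      gt_regions[[p$label]] <- data.frame(
        event = seq_len(n_ev), condition = cond,
        induced_phase = ind_phase, induced_latency = ind_lat,
        amp_gain = drift_gain, stringsAsFactors = FALSE)

      art_gain <- stats::runif(m, 0.5, 1.5)   # per-contact artifact coupling
      # frozen broadband evoked waveform: one realization per subject-region,
      # reused at every active pulse so the transient is phase-locked
      bb_len <- round(1.5 * fs)
      bb_shape <- if (p$evoked_broadband_amp > 0)
        shaped_background(bb_len, fs, config$background_exponent,
                          deterministic_spectrum = TRUE) else NULL
      for (i in seq_len(m)) {
        ci <- (r - 1L) * m + i
        g <- config$contact_falloff^(i - 1L)
        x <- shaped_background(n, fs, config$background_exponent)
        band <- if (p$hfa_suppression > 0) fft_bandpass(x, fs, 70, 110) else NULL
        for (e in seq_len(n_ev)) {
          o <- onsets[e]
          i0 <- time_to_index(o, fs) + 1L      # 1-based sample at the pulse
          if (is_tms[e]) {
            if (p$evoked_amp > 0) {
              len <- min(round(1.5 * fs), n - i0 + 1L)
              tt <- (seq_len(len) - 1L) / fs
              x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
                evoked_waveform(tt, p$evoked_amp * g * drift_gain[e],
                                p$evoked_freq, p$evoked_decay)
            }
            if (p$evoked_broadband_amp > 0) {
              len <- min(bb_len, n - i0 + 1L)
              tt <- (seq_len(len) - 1L) / fs
              x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
                p$evoked_broadband_amp * g * drift_gain[e] *
                exp(-tt / p$evoked_decay) * bb_shape[seq_len(len)]
            }
            if (p$induced_amp > 0) {
              len <- min(round(1.5 * fs), n - i0 + 1L)
              tt <- (seq_len(len) - 1L) / fs
              x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
                induced_waveform(tt, p$induced_amp * g * drift_gain[e],
                                 p$induced_freq, ind_phase[e], ind_lat[e])
            }
            if (p$hfa_suppression > 0) {
              a <- i0 + time_to_index(p$suppression_window[1], fs)
              b <- i0 + time_to_index(p$suppression_window[2], fs) - 1L
              b <- min(b, n)
              x[a:b] <- x[a:b] - p$hfa_suppression * band[a:b]
            }
            if (config$artifact_amplitude > 0) {
              half <- config$artifact_duration / 2
              a <- i0 + time_to_index(-half, fs)
              len <- round(config$artifact_duration * fs)
              tt <- -half + (seq_len(len) - 1L) / fs
              x[a:(a + len - 1L)] <- x[a:(a + len - 1L)] +
                artifact_waveform(tt, config$artifact_amplitude * art_gain[i],
                                  config$artifact_duration)
            }
          } else if (p$sham_click_amp > 0) {
            len <- min(round(0.5 * fs), n - i0 + 1L)
            tt <- (seq_len(len) - 1L) / fs
            x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
              click_waveform(tt, p$sham_click_amp * g)
          }
        }
        data[ci, ] <- gain * (x + line)
        ch_rows[[ci]] <- data.frame(
          name = sprintf("%s-R%d-%d", subj, r, i), subject = subj,
          montage_type = "depth", shaft = sprintf("R%d", r),
          contact_index = i, anatomical_label = p$label, roi = p$label,
          status = "good", exclusion_reason = "none", stringsAsFactors = FALSE)
      }
    }
    ch <- do.call(rbind, ch_rows)
    recordings[[subj]] <- continuous_recording(data, fs, ch$name)
    channels_all[[subj]] <- ch
    events_all[[subj]] <- events
    ground_truth[[subj]] <- list(gain = gain, regions = gt_regions)
  }
  list(recordings = recordings,
       channels = do.call(rbind, c(channels_all, make.row.names = FALSE)),
       events = do.call(rbind, c(events_all, make.row.names = FALSE)),
       ground_truth = ground_truth, config = config)
}

#' Write a synthetic dataset to disk in the pipeline's native formats
#'
#' One binary recording container per subject plus channels/events TSVs and a
#' ground-truth JSON sidecar of the injected parameters.
#' @param dataset output of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in names(dataset$recordings))
    write_recording(dataset$recordings[[subj]],
                    file.path(dir, sprintf("%s_ieeg", subj)))
  write_channels(dataset$channels, file.path(dir, "channels.tsv"))
  write_events(dataset$events, file.path(dir, "events.tsv"))
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
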
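# Preprocessing: re-referencing, stimulation-artifact interpolation,
# line-noise removal, anti-aliased downsampling, epoching.

#' Continuous multi-channel recording
#'
#' @param data channels x samples numeric matrix
#' @param fs sampling rate, Hz
#' @param channel_names unique channel names (length `nrow(data)`)
#' @param start_time time of the first sample, seconds (default 0)
#' @return a `continuous_recording` object
#' @export
continuous_recording <- function(data, fs, channel_names,
                                 start_time = 0) {
  if (!is.matrix(data)) stop_param("data", "must be a channels x samples matrix")
  check_scalar(fs, "fs", lower = 1e-9)
  if (length(channel_names) != nrow(data))
    stop_param("channel_names", "length must match nrow(data)")
  if (anyDuplicated(channel_names))
    stop_param("channel_names", "must be unique")
  flagged <- rowSums(is.na(data)) > 0
  if (any(flagged)) {
    warning(sprintf("NaN samples in channel(s) %s; flagged",
                    paste(channel_names[flagged], collapse = ", ")))
  }
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 start_time = start_time, nan_flagged = channel_names[flagged]),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Re-reference a recording (bipolar depth, common-average grid)
#'
#' Depth contacts are replaced by adjacent-pair differences within each
#' shaft (n contacts yield n-1 bipolar channels); grid/strip contacts have
#' the mean over all good grid/strip channels subtracted per sample.
#' Channels flagged as excluded are omitted from the common average and from
#' bipolar pairing.
#'
#' @param recording a [continuous_recording()]
#' @param channels channel table rows for this recording's channels (see
#'   [read_channels()] for the schema)
#' @return list with the re-referenced `recording` and the derived `channels`
#'   table
#' @export
rereference <- function(recording, channels) {
  stopifnot(inherits(recording, "continuous_recording"))
  channels <- channels[match(recording$channel_names, channels$name), , drop = FALSE]
  if (anyNA(channels$name))
    stop("channel table does not cover all recording channels")
  bad_type <- !channels$montage_type %in% c("depth", "grid")
  if (any(bad_type))
    stop(sprintf("unknown montage type for channel(s): %s",
                 paste(channels$name[bad_type], collapse = ", ")))
  good <- channels$status == "good"
  out_rows <- list()
  out_data <- list()

  is_grid <- channels$montage_type == "grid"
  if (any(is_grid)) {
    ref_idx <- which(is_grid & good)
    if (!length(ref_idx))
      stop("no good grid/strip channels to form a common average")
    ca <- colMeans(recording$data[ref_idx, , drop = FALSE])
    for (i in which(is_grid & good)) {
      out_data[[length(out_data) + 1L]] <- recording$data[i, ] - ca
      out_rows[[length(out_rows) + 1L]] <- channels[i, , drop = FALSE]
    }
  }

  is_depth <- channels$montage_type == "depth"
  if (any(is_depth)) {
    for (shaft in unique(channels$shaft[is_depth])) {
      idx <- which(is_depth & channels$shaft == shaft & good)
      idx <- idx[order(channels$contact_index[idx])]
      if (length(idx) < 2L) {
        warning(sprintf("shaft %s has a single usable contact; dropped", shaft))
        next
      }
      ords <- channels$contact_index[idx]
      for (j in seq_len(length(idx) - 1L)) {
        if (ords[j + 1L] != ords[j] + 1L) next   # gap from exclusion: no pair
        a <- idx[j]; b <- idx[j + 1L]
        out_data[[length(out_data) + 1L]] <-
          recording$data[a, ] - recording$data[b, ]
        row <- channels[a, , drop = FALSE]
        row$name <- paste0(channels$name[a], "-", channels$name[b])
        out_rows[[length(out_rows) + 1L]] <- row
      }
    }
  }
  if (!length(out_data)) stop("re-referencing produced no channels")
  new_ch <- do.call(rbind, c(out_rows, make.row.names = FALSE))
  rec <- continuous_recording(do.call(rbind, out_data), recording$fs,
                              new_ch$name, recording$start_time)
  list(recording = rec, channels = new_ch)
}

#' Interpolate the stimulation artifact in a single trace
#'
#' Replaces the interval `[onset - 25 ms, onset + 25 ms)` with a weighted sum
#' of the reversed 50 ms flanks: `rev(pre) * w_down + rev(post) * w_up`,
#' where `w_down` ramps linearly 1 to 0 across the window and
#' `w_up = 1 - w_down`, so the replacement joins the flanking samples
#' continuously and a constant trace is left unchanged. The operation is
#' idempotent because it depends only on samples outside the window.
#'
#' @param x numeric trace
#' @param fs sampling rate, Hz
#' @param onset stimulation time, seconds relative to the first sample
#' @param half_width half-width of the replaced window, seconds (default 0.025)
#' @param flank flank duration used to synthesize the replacement, seconds
#'   (default 0.05)
#' @param trial label used in error messages
#' @return the trace with the artifact window replaced
#' @export
interpolate_artifact <- function(x, fs, onset, half_width = 0.025,
                                 flank = 0.05, trial = "?") {
  a <- time_to_index(onset - half_width, fs) + 1L  # first replaced sample
  b <- time_to_index(onset + half_width, fs)       # last replaced sample
  L <- b - a + 1L
  fl <- round(flank * fs)
  if (a - fl < 1L || b + fl > length(x))
    stop(sprintf("trial %s: fewer than %g ms of flanking samples around the artifact",
                 trial, flank * 1000))
  pre <- x[(a - fl):(a - 1L)]
  post <- x[(b + 1L):(b + fl)]
  if (fl != L) {   # resample flanks linearly to the replacement length
    pre <- stats::approx(seq_along(pre), pre, n = L)$y
    post <- stats::approx(seq_along(post), post, n = L)$y
  }
  w_down <- if (L > 1L) 1 - (seq_len(L) - 1L) / (L - 1L) else 0.5
  x[a:b] <- rev(pre) * w_down + rev(post) * (1 - w_down)
  x
}

#' Interpolate the stimulation artifact at every event of a recording
#'
#' Applied per channel on the continuous record, before epoching, so the
#' replacement introduces no epoch-edge effects.
#' @param recording a [continuous_recording()]
#' @param events event table (uses `onset_s`)
#' @inheritParams interpolate_artifact
#' @return the cleaned recording
#' @export
interpolate_artifacts <- function(recording, events, half_width = 0.025,
                                  flank = 0.05) {
  stopifnot(inherits(recording, "continuous_recording"))
  for (e in seq_len(nrow(events))) {
    onset <- events$onset_s[e] - recording$start_time
    for (c in seq_len(nrow(recording$data)))
      recording$data[c, ] <- interpolate_artifact(
        recording$data[c, ], recording$fs, onset,
        half_width = half_width, flank = flank, trial = as.character(e))
  }
  recording
}

#' Remove line noise at a base frequency and its harmonics
#'
#' At `base_freq` and every harmonic below Nyquist, a sinusoidal component is
#' tested with the Thomson multitaper harmonic F-test (Bonferroni-corrected
#' over the tested harmonics); significant components are removed by exact
#' least-squares sinusoid subtraction over the full trace. Frequencies
#' without a significant component are left untouched.
#'
#' @param x numeric trace (>= 1 s long)
#' @param fs sampling rate, Hz
#' @param base_freq line frequency, Hz (default 60)
#' @param alpha significance level before Bonferroni correction (default 0.05)
#' @param nw time-bandwidth product of the detection test
#' @return the cleaned trace
#' @export
remove_line_noise <- function(x, fs, base_freq = 60, alpha = 0.05, nw = 4) {
  n <- length(x)
  if (n < fs) stop("trace must be at least 1 s long")
  harmonics <- seq(base_freq, fs / 2 - 1e-9, by = base_freq)
  if (!length(harmonics)) return(x)
  # detection on a centered window capped for the taper eigenproblem
  n_det <- min(n, 2048L)
  off <- (n - n_det) %/% 2L
  seg <- x[(off + 1L):(off + n_det)]
  thr <- stats::qf(1 - alpha / length(harmonics), 2,
                   2 * (2 * nw - 1) - 2)
  t <- (seq_len(n) - 1L) / fs
  for (f0 in harmonics) {
    ft <- harmonic_ftest(seg, fs, f0, nw = nw)
    if (ft$F > thr) {
      C <- cos(2 * pi * f0 * t); S <- sin(2 * pi * f0 * t)
      fit <- stats::lm.fit(cbind(C, S), x)
      x <- x - cbind(C, S) %*% fit$coefficients
      x <- drop(x)
    }
  }
  x
}

#' Remove line noise from every channel of a recording
#' @inheritParams remove_line_noise
#' @param recording a [continuous_recording()]
#' @return the cleaned recording
#' @export
remove_line_noise_recording <- function(recording, base_freq = 60,
                                        alpha = 0.05, nw = 4) {
  stopifnot(inherits(recording, "continuous_recording"))
  for (c in seq_len(nrow(recording$data)))
    recording$data[c, ] <- remove_line_noise(recording$data[c, ], recording$fs,
                                             base_freq = base_freq,
                                             alpha = alpha, nw = nw)
  recording
}

# Windowed-sinc (Hamming) anti-alias FIR with cutoff at 0.8 x the target
# Nyquist; linear phase compensated exactly via the integer group delay.
antialias_filter <- function(x, q) {
  ord <- 2L * ceiling(16.5 * q)           # transition ~0.1 x target fs
  h <- signal::fir1(ord, 0.8 / q, type = "low")
  h <- h / sum(h)                          # exact unity DC gain
  n <- length(x)
  y <- signal::fftfilt(h, c(x, numeric(ord)))
  y[(ord / 2 + 1L):(ord / 2 + n)]
}

#' Downsample a recording with anti-alias filtering
#'
#' @param recording a [continuous_recording()] (or a numeric vector with
#'   `fs` supplied)
#' @param target_fs target sampling rate, Hz; must divide the current rate
#' @param fs sampling rate when `recording` is a plain vector
#' @return downsampled recording (or vector)
#' @export
downsample <- function(recording, target_fs = 500, fs = NULL) {
  if (is.numeric(recording) && !is.null(fs)) {
    if (target_fs > fs) stop("target_fs exceeds the sampling rate")
    q <- fs / target_fs
    if (abs(q - round(q)) > 1e-9)
      stop("target_fs must divide the sampling rate")
    q <- as.integer(round(q))
    if (q == 1L) return(recording)
    y <- antialias_filter(recording, q)
    return(y[seq(1L, length(y), by = q)])
  }
  stopifnot(inherits(recording, "continuous_recording"))
  if (target_fs > recording$fs) stop("target_fs exceeds the sampling rate")
  q <- recording$fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("target_fs must divide the sampling rate")
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  newdata <- t(apply(recording$data, 1, function(x) {
    y <- antialias_filter(x, q)
    y[seq(1L, length(y), by = q)]
  }))
  continuous_recording(newdata, target_fs, recording$channel_names,
                       recording$start_time)
}

#' Segment a recording into stimulation-locked epochs
#'
#' One trial per event, spanning `[t0, t0 + duration)` seconds around each
#' onset. Events whose window falls outside the recording are dropped with a
#' warning; trial order is otherwise preserved.
#'
#' @param recording a [continuous_recording()]
#' @param events event table with `onset_s`, `condition`, `target`
#' @param t0 epoch start relative to stimulation, seconds (default -0.5)
#' @param duration epoch length, seconds (default 2.5)
#' @return an `epoch_set`: list with `data` (trials x channels x samples),
#'   `fs`, `t0`, `duration`, `condition`, `target`, `subject`,
#'   `channel_names`, `times`
#' @export
epoch_recording <- function(recording, events, t0 = -0.5, duration = 2.5) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (!(t0 < 0 && 0 < t0 + duration))
    stop_param("t0", "epoch must span the stimulation time (t0 < 0 < t0 + duration)")
  fs <- recording$fs
  n_samp <- round(duration * fs)
  n_total <- ncol(recording$data)
  starts <- time_to_index(events$onset_s - recording$start_time + t0, fs) + 1L
  ok <- starts >= 1L & (starts + n_samp - 1L) <= n_total
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge; dropped",
                    sum(!ok)))
  if (!any(ok)) stop("no epochable events")
  keep <- which(ok)
  n_ch <- nrow(recording$data)
  data <- array(NA_real_, c(length(keep), n_ch, n_samp))
  for (k in seq_along(keep)) {
    i0 <- starts[keep[k]]
    data[k, , ] <- recording$data[, i0:(i0 + n_samp - 1L)]
  }
  structure(list(
    data = data, fs = fs, t0 = t0, duration = duration,
    condition = events$condition[keep],
    target = if ("target" %in% names(events)) events$target[keep] else NULL,
    subject = if ("subject" %in% names(events)) events$subject[keep][1] else NA_character_,
    channel_names = recording$channel_names,
    times = t0 + (seq_len(n_samp) - 1L) / fs), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$t0,
              x$t0 + x$duration))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Select trials of an epoch set
#' @param epochs an `epoch_set`
#' @param idx trial indices (logical or integer)
#' @return the subset `epoch_set`
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$condition <- epochs$condition[idx]
  if (!is.null(epochs$target)) epochs$target <- epochs$target[idx]
  epochs
}
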
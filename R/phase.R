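# Inter-trial phase locking (IPL / phase-locking value) in the theta band,
# with trial-count matching, mirror buffering and TMS-minus-sham difference.

#' Mean resultant vector length of a set of phases
#'
#' The core phase-locking statistic: `|mean(exp(1i * phases))|`. Equals 1
#' for identical phases and 0 for phases spread uniformly around the circle.
#' @param phases numeric vector of phases, radians
#' @return scalar in `[0, 1]`
#' @export
phase_locking_value <- function(phases) {
  if (!length(phases)) stop("no phases supplied")
  Mod(mean(exp(1i * phases)))
}

#' Match trial counts between conditions by random subsampling
#'
#' Phase locking is biased by trial count, so both conditions are subsampled
#' without replacement to the smaller count. Uses the caller's RNG state;
#' seed it for reproducibility.
#'
#' @param n_tms,n_sham trial counts (both >= 2)
#' @return list with integer index vectors `tms` and `sham`, each of length
#'   `min(n_tms, n_sham)`
#' @export
match_trial_counts <- function(n_tms, n_sham) {
  check_scalar(n_tms, "n_tms", lower = 2)
  check_scalar(n_sham, "n_sham", lower = 2)
  n <- min(n_tms, n_sham)
  list(tms = sort(sample.int(n_tms, n)), sham = sort(sample.int(n_sham, n)))
}

#' Mirror-buffer a trace
#'
#' Prepends the reversed leading edge and appends the reversed trailing edge,
#' protecting convolution outputs near the edges; the buffers are clipped
#' downstream.
#' @param x numeric trace
#' @param n_buffer buffer length, samples (must not exceed `length(x)`)
#' @return padded trace of length `length(x) + 2 * n_buffer`
#' @export
mirror_buffer <- function(x, n_buffer) {
  n_buffer <- as.integer(n_buffer)
  if (n_buffer < 0L) stop_param("n_buffer", "must be >= 0")
  if (n_buffer > length(x)) stop("trace shorter than the mirror buffer")
  if (n_buffer == 0L) return(x)
  c(rev(x[seq_len(n_buffer)]), x, rev(x[(length(x) - n_buffer + 1L):length(x)]))
}

# Complex multitaper wavelet coefficients for one channel at one frequency:
# trials x times matrix per taper; IPL is computed per taper from the
# normalized coefficients and averaged across tapers.
mt_wavelet_itc <- function(trials_mat, fs, f, nw, n_cycles, n_buffer,
                           min_concentration = 0.9) {
  # trials_mat: trials x samples
  n <- ncol(trials_mat)
  win <- round(n_cycles / f * fs)
  dp <- dpss_tapers(win, nw = nw)
  keep <- dp$concentration >= min_concentration
  if (!any(keep)) keep[1] <- TRUE
  taps <- dp$tapers[, keep, drop = FALSE]
  padded <- t(apply(trials_mat, 1, mirror_buffer, n_buffer = n_buffer))
  np <- ncol(padded)
  half <- win %/% 2L
  nfft <- stats::nextn(np + win - 1L)
  Xf <- stats::mvfft(rbind(t(padded), matrix(0, nfft - np, nrow(padded))))
  tt <- (seq_len(win) - 1L - half) / fs
  itc_acc <- 0
  for (k in seq_len(ncol(taps))) {
    w <- taps[, k] * exp(2i * pi * f * tt)
    W <- stats::fft(c(w, complex(real = numeric(nfft - win))))
    conv <- stats::mvfft(Xf * W, inverse = TRUE) / nfft
    centre <- conv[(half + 1L):(half + np), , drop = FALSE]  # times x trials
    core <- centre[(n_buffer + 1L):(n_buffer + n), , drop = FALSE]
    z <- core / pmax(Mod(core), .Machine$double.eps)
    itc_acc <- itc_acc + Mod(rowMeans(z))
  }
  itc_acc / ncol(taps)    # times vector
}

#' Inter-trial phase locking across an epoch set
#'
#' Continuous theta-band phase is extracted per trial with DPSS-tapered
#' complex wavelets (window length `n_cycles / f` per frequency), after
#' mirror-buffering each trial; IPL at each time and frequency is the mean
#' resultant vector length of the per-trial phases, averaged across tapers.
#'
#' @param epochs an `epoch_set` with at least 2 trials (match trial counts
#'   between conditions first; see [match_trial_counts()])
#' @param freqs analysis frequencies, Hz (default 3-8 in 1 Hz steps)
#' @param nw time-bandwidth product (default 4)
#' @param n_cycles window length in cycles (default 2)
#' @param buffer mirror-buffer duration, seconds (default 0.45)
#' @return `ipl_trace` object: `ipl` (channels x freqs x times in `[0, 1]`),
#'   `freqs`, `times`, `n_trials`
#' @export
inter_trial_phase_locking <- function(epochs, freqs = 3:8, nw = 4,
                                      n_cycles = 2, buffer = 0.45) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 2L) stop("phase locking is undefined for fewer than 2 trials")
  n_buffer <- round(buffer * epochs$fs)
  ipl <- array(NA_real_, c(d[2], length(freqs), d[3]))
  for (c in seq_len(d[2])) {
    tm <- epochs$data[, c, , drop = TRUE]
    if (d[1] == 1L) tm <- matrix(tm, nrow = 1)
    for (fi in seq_along(freqs))
      ipl[c, fi, ] <- mt_wavelet_itc(tm, epochs$fs, freqs[fi], nw, n_cycles,
                                     n_buffer)
  }
  structure(list(ipl = ipl, freqs = freqs, times = epochs$times,
                 n_trials = d[1], channel_names = epochs$channel_names,
                 subject = epochs$subject),
            class = "ipl_trace")
}

#' Baseline-corrected TMS-minus-sham IPL difference
#'
#' Each condition's IPL has its mean over the pre-stimulus baseline interval
#' subtracted (per channel and frequency); the difference of the corrected
#' traces is the TMS-related phase-locking measure.
#'
#' @param ipl_tms,ipl_sham `ipl_trace` objects on identical time/frequency
#'   grids, computed at matched trial counts
#' @param baseline_window baseline interval, seconds (default
#'   `c(-0.5, -0.05)`)
#' @return `delta_ipl` object with `delta`, `ipl_tms`, `ipl_sham` (corrected
#'   arrays channels x freqs x times), `freqs`, `times`, `n_matched`
#' @export
delta_ipl <- function(ipl_tms, ipl_sham, baseline_window = c(-0.5, -0.05)) {
  stopifnot(inherits(ipl_tms, "ipl_trace"), inherits(ipl_sham, "ipl_trace"))
  if (!isTRUE(all.equal(ipl_tms$times, ipl_sham$times)) ||
      !isTRUE(all.equal(ipl_tms$freqs, ipl_sham$freqs)))
    stop("TMS and sham IPL were computed on different time/frequency grids")
  if (ipl_tms$n_trials != ipl_sham$n_trials)
    warning("trial counts differ between conditions; IPL bias is not matched")
  bsel <- ipl_tms$times >= baseline_window[1] & ipl_tms$times < baseline_window[2]
  if (!any(bsel)) stop("baseline window contains no IPL samples")
  correct <- function(a) sweep(a, c(1, 2),
                               apply(a[, , bsel, drop = FALSE], c(1, 2), mean), "-")
  tms_c <- correct(ipl_tms$ipl)
  sham_c <- correct(ipl_sham$ipl)
  structure(list(delta = tms_c - sham_c, ipl_tms = tms_c, ipl_sham = sham_c,
                 freqs = ipl_tms$freqs, times = ipl_tms$times,
                 n_matched = min(ipl_tms$n_trials, ipl_sham$n_trials),
                 channel_names = ipl_tms$channel_names,
                 subject = ipl_tms$subject),
            class = "delta_ipl")
}

#' Compute the matched-count ΔIPL for one subject's epochs
#'
#' Convenience wrapper: subsamples trials to equal counts, computes IPL per
#' condition and returns the baseline-corrected difference.
#' @param epochs an `epoch_set` containing both conditions
#' @inheritParams inter_trial_phase_locking
#' @param baseline_window baseline interval, seconds
#' @return a [delta_ipl()] object
#' @export
compute_delta_ipl <- function(epochs, freqs = 3:8, nw = 4, n_cycles = 2,
                              buffer = 0.45, baseline_window = c(-0.5, -0.05)) {
  tms_idx <- which(epochs$condition == "tms")
  sham_idx <- which(epochs$condition == "sham")
  sel <- match_trial_counts(length(tms_idx), length(sham_idx))
  ipl_t <- inter_trial_phase_locking(subset_trials(epochs, tms_idx[sel$tms]),
                                     freqs, nw, n_cycles, buffer)
  ipl_s <- inter_trial_phase_locking(subset_trials(epochs, sham_idx[sel$sham]),
                                     freqs, nw, n_cycles, buffer)
  delta_ipl(ipl_t, ipl_s, baseline_window)
}

#' Window-averaged ΔIPL per contact
#'
#' Averages the ΔIPL over in-band frequencies and over 500 ms windows
#' starting 100 ms to 900 ms after stimulation in 100 ms steps.
#' @param dipl a [delta_ipl()] object
#' @param starts window start times, seconds
#' @param width window width, seconds (default 0.5)
#' @return channels x windows matrix with `window_starts` attribute
#' @export
windowed_delta_ipl <- function(dipl, starts = seq(0.1, 0.9, by = 0.1),
                               width = 0.5) {
  stopifnot(inherits(dipl, "delta_ipl"))
  out <- matrix(NA_real_, dim(dipl$delta)[1], length(starts))
  for (w in seq_along(starts)) {
    tsel <- dipl$times >= starts[w] & dipl$times < starts[w] + width
    if (!any(tsel)) stop(sprintf("window at %g s outside the IPL trace", starts[w]))
    out[, w] <- apply(dipl$delta[, , tsel, drop = FALSE], 1, mean)
  }
  rownames(out) <- dipl$channel_names
  attr(out, "window_starts") <- starts
  out
}
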
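# Windowed multitaper band power with pre-stimulus baseline correction, and
# Morlet time-frequency decomposition.

#' Frequency-band specification
#'
#' Presets follow the pipeline's canonical bands: theta 3-8 Hz and gamma
#' 30-50 Hz analyzed in 500 ms windows, high-frequency activity (HFA)
#' 70-110 Hz in 250 ms windows (high-frequency power fluctuates at faster
#' timescales). Note the HFA window is deliberately short relative to one
#' 3 Hz-style cycle rule; no cycle constraint is enforced.
#'
#' @param name `"theta"`, `"gamma"`, `"hfa"`, or `"custom"`
#' @param f_lo,f_hi band edges, Hz (required for `"custom"`)
#' @param window_width analysis window, seconds (required for `"custom"`)
#' @return a `band_spec` object
#' @export
band_spec <- function(name = c("theta", "gamma", "hfa", "custom"),
                      f_lo = NULL, f_hi = NULL, window_width = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    theta = list(3, 8, 0.5), gamma = list(30, 50, 0.5),
    hfa = list(70, 110, 0.25), custom = list(f_lo, f_hi, window_width))
  if (any(vapply(preset, is.null, logical(1))))
    stop_param("band", "custom bands need f_lo, f_hi and window_width")
  f_lo <- preset[[1]]; f_hi <- preset[[2]]; width <- preset[[3]]
  if (!(f_lo > 0 && f_lo < f_hi))
    stop_param("band", "must satisfy 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 window_width = width), class = "band_spec")
}

# Extract the samples x (trials*channels) matrix for a half-open time window
# [start, start + width) on the epoch time axis, vectorized over trials and
# channels. Returns a matrix whose columns run trial-fastest.
window_matrix <- function(epochs, start, width) {
  fs <- epochs$fs
  i0 <- time_to_index(start - epochs$t0, fs) + 1L
  len <- round(width * fs)
  n_samp <- dim(epochs$data)[3]
  if (i0 < 1L || i0 + len - 1L > n_samp)
    stop(sprintf("window [%g, %g) s falls outside the epochs", start, start + width))
  seg <- epochs$data[, , i0:(i0 + len - 1L), drop = FALSE]
  d <- dim(seg)
  # -> samples x (trials*channels), trial index fastest
  matrix(aperm(seg, c(3, 1, 2)), nrow = d[3])
}

#' Multitaper log band power of a single segment
#'
#' DPSS tapers with the given time-bandwidth product, tapers below the
#' concentration threshold dropped, PSD averaged over tapers, then
#' log-transformed per frequency and averaged over in-band frequencies.
#'
#' @param x numeric segment (or samples x series matrix)
#' @param fs sampling rate, Hz
#' @param band a [band_spec()]; when `x` is a vector its length must equal
#'   `band$window_width * fs`
#' @param nw time-bandwidth product (default 4)
#' @param min_concentration taper concentration threshold (default 0.9)
#' @param enforce_width check the segment length against the band's window
#' @return scalar (or per-series vector) natural-log band power
#' @export
multitaper_band_power <- function(x, fs, band, nw = 4,
                                  min_concentration = 0.9,
                                  enforce_width = TRUE) {
  stopifnot(inherits(band, "band_spec"))
  n <- if (is.matrix(x)) nrow(x) else length(x)
  want <- round(band$window_width * fs)
  if (enforce_width && n != want)
    stop(sprintf("segment has %d samples; band '%s' requires %d (%.3g s at %g Hz)",
                 n, band$name, want, band$window_width, fs))
  mt_band_logpower(x, fs, band$f_lo, band$f_hi, nw = nw,
                   min_concentration = min_concentration)
}

#' Post-stimulation window grid
#'
#' Successive overlapping windows spaced 100 ms apart, starting 50 ms after
#' stimulation (to clear the interpolated artifact) with the last start at
#' 850 ms.
#' @return numeric vector of window start times, seconds
#' @export
power_window_starts <- function() seq(0.05, 0.85, by = 0.1)

#' Windowed multitaper band power across an epoch set
#'
#' @param epochs an `epoch_set`
#' @param band a [band_spec()]
#' @param starts window start times, seconds (default [power_window_starts()])
#' @inheritParams multitaper_band_power
#' @return `band_power` object: `values` (trials x channels x windows raw
#'   natural-log power), `window_starts`, `band`
#' @export
windowed_power <- function(epochs, band, starts = power_window_starts(),
                           nw = 4, min_concentration = 0.9) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_spec"))
  d <- dim(epochs$data)
  vals <- array(NA_real_, c(d[1], d[2], length(starts)))
  for (w in seq_along(starts)) {
    X <- window_matrix(epochs, starts[w], band$window_width)
    lp <- mt_band_logpower(X, epochs$fs, band$f_lo, band$f_hi, nw = nw,
                           min_concentration = min_concentration)
    vals[, , w] <- matrix(lp, d[1], d[2])
  }
  structure(list(values = vals, window_starts = starts, band = band,
                 condition = epochs$condition, subject = epochs$subject,
                 channel_names = epochs$channel_names),
            class = "band_power")
}

#' Pre-stimulus baseline band power
#'
#' Multitaper log band power in the 450 ms window `[-0.5, -0.05)` s — the
#' baseline period buffered by 50 ms from the stimulation artifact — one
#' value per trial and channel.
#'
#' @inheritParams windowed_power
#' @param window baseline interval `(start, end)`, seconds (default
#'   `c(-0.5, -0.05)`)
#' @return trials x channels matrix of natural-log baseline power
#' @export
baseline_power <- function(epochs, band, window = c(-0.5, -0.05),
                           nw = 4, min_concentration = 0.9) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$t0 > window[1] + 1e-9)
    stop(sprintf("epochs start at %g s; baseline window needs %g s of pre-stimulus data",
                 epochs$t0, window[1]))
  X <- window_matrix(epochs, window[1], window[2] - window[1])
  lp <- mt_band_logpower(X, epochs$fs, band$f_lo, band$f_hi, nw = nw,
                         min_concentration = min_concentration)
  d <- dim(epochs$data)
  matrix(lp, d[1], d[2])
}

#' Baseline-corrected windowed band power
#'
#' Subtracts each trial's pre-stimulus baseline log power from every
#' post-stimulation window, making the values gain-invariant log power
#' ratios.
#' @inheritParams windowed_power
#' @param baseline_window baseline interval, seconds
#' @return `band_power` object with baseline-corrected `values` and the
#'   `baseline` matrix attached
#' @export
band_power <- function(epochs, band, starts = power_window_starts(),
                       baseline_window = c(-0.5, -0.05), nw = 4,
                       min_concentration = 0.9) {
  bp <- windowed_power(epochs, band, starts, nw, min_concentration)
  bl <- baseline_power(epochs, band, baseline_window, nw, min_concentration)
  bp$values <- sweep(bp$values, c(1, 2), bl, "-")
  bp$baseline <- bl
  bp
}

#' Morlet time-frequency decomposition
#'
#' Complex Morlet convolution (fixed number of cycles at every frequency) at
#' log-spaced frequencies; power is the squared magnitude, log-transformed
#' and baseline-corrected per trial and frequency using the mean log power
#' over the baseline interval.
#'
#' @param epochs an `epoch_set` (artifact-interpolated)
#' @param freqs analysis frequencies, Hz (default 25 log-spaced in
#'   `[3, 110]`)
#' @param n_cycles wavelet length in cycles (default 3)
#' @param baseline_window baseline interval, seconds; `NULL` skips correction
#' @param time_decim keep every `time_decim`-th sample of the output
#' @return `tfr` object: `power` (trials x channels x freqs x times, natural
#'   log), `freqs`, `times`
#' @export
morlet_tfr <- function(epochs, freqs = tfr_default_freqs(), n_cycles = 3,
                       baseline_window = c(-0.5, -0.05), time_decim = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  fs <- epochs$fs
  n <- d[3]
  keep_t <- seq(1L, n, by = time_decim)
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)  # samples x (tr*ch)
  power <- array(NA_real_, c(d[1], d[2], length(freqs), length(keep_t)))
  # mirror-pad the epochs so wavelets never run off the data edge
  npad <- min(n, max(vapply(freqs, function(f)
    round(5 * n_cycles / (2 * pi * f) * fs), numeric(1))))
  Xp <- rbind(X[npad:1, , drop = FALSE], X, X[n:(n - npad + 1L), , drop = FALSE])
  np <- nrow(Xp)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- n_cycles / (2 * pi * f)
    half <- min(round(5 * sigma * fs), n - 1L)
    tt <- (-half:half) / fs
    g <- exp(-tt^2 / (2 * sigma^2))
    w <- exp(2i * pi * f * tt) * g
    w <- w - g * (sum(w) / sum(g))        # zero-mean: reject DC exactly
    w <- w / sqrt(sum(Mod(w)^2))
    L <- length(w)
    nfft <- stats::nextn(np + L - 1L)
    W <- stats::fft(c(w, complex(real = numeric(nfft - L))))
    Xf <- stats::mvfft(rbind(Xp, matrix(0, nfft - np, ncol(Xp))))
    conv <- stats::mvfft(Xf * W, inverse = TRUE) / nfft
    centre <- conv[(half + npad + 1L):(half + npad + n), , drop = FALSE]
    p <- log(pmax(Mod(centre[keep_t, , drop = FALSE])^2, .Machine$double.eps))
    power[, , fi, ] <- array(t(p), c(d[1], d[2], length(keep_t)))
  }
  times <- epochs$times[keep_t]
  if (!is.null(baseline_window)) {
    bsel <- times >= baseline_window[1] & times < baseline_window[2]
    if (!any(bsel)) stop("baseline window contains no TFR samples")
    bl <- apply(power[, , , bsel, drop = FALSE], c(1, 2, 3), mean)
    power <- sweep(power, c(1, 2, 3), bl, "-")
  }
  structure(list(power = power, freqs = freqs, times = times,
                 condition = epochs$condition, subject = epochs$subject,
                 channel_names = epochs$channel_names),
            class = "tfr")
}

#' Default TFR frequency grid: 25 log-spaced frequencies, 3-110 Hz
#' @return numeric vector of frequencies, Hz
#' @export
tfr_default_freqs <- function() exp(seq(log(3), log(110), length.out = 25))

#' Average TFR power into band x window bins
#'
#' Non-overlapping windows (default 100 ms from 0 to 1 s) with in-band
#' frequency bins averaged — the windowing used for subcortical response
#' timecourses.
#'
#' @param tfr a [morlet_tfr()] result
#' @param bands list of [band_spec()] (defaults to theta/gamma/hfa)
#' @param width window width, seconds (default 0.1)
#' @param span `(start, end)` of the covered post-stimulation period
#' @return list with `values` (trials x channels x bands x windows),
#'   `window_starts`, `bands`
#' @export
windowed_tfr_power <- function(tfr, bands = list(band_spec("theta"),
                                                 band_spec("gamma"),
                                                 band_spec("hfa")),
                               width = 0.1, span = c(0, 1)) {
  stopifnot(inherits(tfr, "tfr"))
  starts <- seq(span[1], span[2] - width + 1e-9, by = width)
  d <- dim(tfr$power)
  vals <- array(NA_real_, c(d[1], d[2], length(bands), length(starts)))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    fsel <- tfr$freqs >= b$f_lo & tfr$freqs <= b$f_hi
    if (!any(fsel)) stop(sprintf("no TFR frequencies inside band %s", b$name))
    for (w in seq_along(starts)) {
      tsel <- tfr$times >= starts[w] & tfr$times < starts[w] + width
      vals[, , bi, w] <- apply(
        tfr$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
    }
  }
  list(values = vals, window_starts = starts, bands = bands)
}
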
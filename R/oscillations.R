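# Periodic/aperiodic spectral parameterization and per-trial theta
# oscillation detection. The model follows the "fit oscillations and
# one-over-f" family: a log10-power vs log10-frequency aperiodic line plus
# Gaussian peaks fitted iteratively on the residual.

gaussian_peak <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

# OLS aperiodic line with one robust refit that ignores the largest positive
# residuals (peaks must not pull the line up)
fit_aperiodic <- function(logf, logp) {
  X <- cbind(1, logf)
  co <- stats::lm.fit(X, logp)$coefficients
  r <- logp - drop(X %*% co)
  keep <- r <= stats::quantile(r, 0.75)
  co <- stats::lm.fit(X[keep, , drop = FALSE], logp[keep])$coefficients
  co
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Fits a line to log10 power vs log10 frequency (aperiodic component,
#' without a knee), then adds Gaussian peaks largest-residual-first while
#' the maximum residual exceeds `peak_threshold` times the residual SD and
#' the width constraints hold; finally the aperiodic line is refit on the
#' peak-removed spectrum.
#'
#' @param freqs frequencies, Hz (resolution <= 1 Hz recommended)
#' @param psd strictly positive power values at `freqs`
#' @param fit_range frequency range of the fit, Hz (default `c(3, 50)`)
#' @param peak_threshold detection threshold in residual SDs (default 3)
#' @param width_limits allowed peak widths (2 x Gaussian SD), Hz
#'   (default `c(0.5, 12)`)
#' @param max_peaks maximum number of peaks (default 6)
#' @return `spectral_model` object: `aperiodic` (`offset`, `exponent`; a
#'   negative exponent triggers a warning), `peaks` data.frame (`center`,
#'   `amplitude` in log10-power units above the aperiodic line, `width`),
#'   `residual_sd`, `fit_range`
#' @export
fit_spectral_model <- function(freqs, psd, fit_range = c(3, 50),
                               peak_threshold = 3, width_limits = c(0.5, 12),
                               max_peaks = 6) {
  if (any(psd <= 0) || any(!is.finite(psd)))
    stop("power spectrum must be strictly positive and finite")
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2]
  if (sum(sel) < 6) stop("too few frequencies inside the fit range")
  f <- freqs[sel]; p <- psd[sel]
  logf <- log10(f); logp <- log10(p)

  ap <- fit_aperiodic(logf, logp)
  resid <- logp - (ap[1] + ap[2] * logf)
  sd_lim <- width_limits / 2          # Gaussian SD limits
  peaks <- list()
  for (it in seq_len(max_peaks)) {
    sdr <- stats::sd(resid)
    imax <- which.max(resid)
    if (resid[imax] <= peak_threshold * sdr) break
    c0 <- f[imax]; h0 <- resid[imax]
    obj <- function(par)
      sum((resid - gaussian_peak(f, par[1], par[2], par[3]))^2)
    opt <- stats::optim(c(c0, h0, 1),
                        obj, method = "L-BFGS-B",
                        lower = c(fit_range[1], h0 * 0.05, sd_lim[1]),
                        upper = c(fit_range[2], h0 * 2, sd_lim[2]))
    pk <- opt$par
    peaks[[length(peaks) + 1L]] <-
      data.frame(center = pk[1], amplitude = pk[2], width = 2 * pk[3])
    resid <- resid - gaussian_peak(f, pk[1], pk[2], pk[3])
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks)
  else data.frame(center = numeric(), amplitude = numeric(), width = numeric())
  # drop peaks within one SD of a fit-range edge: their Gaussians are
  # truncated by the range and mostly reflect edge leakage, not oscillations
  if (nrow(peaks)) {
    sd_g <- peaks$width / 2
    keep_pk <- (peaks$center - fit_range[1]) >= sd_g &
      (fit_range[2] - peaks$center) >= sd_g
    peaks <- peaks[keep_pk, , drop = FALSE]
    rownames(peaks) <- NULL
  }

  # aperiodic refit on the peak-removed spectrum
  peak_sum <- if (nrow(peaks)) Reduce(`+`, lapply(seq_len(nrow(peaks)), function(i)
    gaussian_peak(f, peaks$center[i], peaks$amplitude[i], peaks$width[i] / 2)))
  else 0
  co <- stats::lm.fit(cbind(1, logf), logp - peak_sum)$coefficients
  offset <- unname(co[1]); exponent <- unname(-co[2])
  if (exponent < 0)
    warning("fitted aperiodic exponent is negative (non-1/f spectrum)")
  final_resid <- logp - (co[1] + co[2] * logf) - peak_sum
  structure(list(aperiodic = c(offset = offset, exponent = exponent),
                 peaks = peaks, residual_sd = stats::sd(final_resid),
                 fit_range = fit_range), class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model> offset %.3f, exponent %.3f, %d peak(s), resid sd %.3f\n",
              x$aperiodic["offset"], x$aperiodic["exponent"], nrow(x$peaks),
              x$residual_sd))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Per-trial theta peak amplitude
#'
#' Multitaper PSD of the 1 s post-stimulation window (default 50-1050 ms),
#' spectral-model fit over 3-50 Hz, and the largest-amplitude detected peak
#' whose center lies in the theta range; `NA` when no such peak exists.
#'
#' @param x single-trial single-channel waveform on the epoch time axis
#' @param fs sampling rate, Hz
#' @param t0 time of the first sample relative to stimulation, seconds
#' @param window analysis window `(start, end)`, seconds (default
#'   `c(0.05, 1.05)`)
#' @param theta_range peak-center acceptance range, Hz (default `c(3, 8)`)
#' @param nw time-bandwidth product of the PSD (default 3: on single-trial
#'   1 s windows this keeps narrowband bursts peak-like instead of smearing
#'   them into the aperiodic component, at acceptable estimator variance)
#' @param ... passed to [fit_spectral_model()]
#' @return peak amplitude (log10-power units) or `NA` if absent
#' @export
trial_theta_peak <- function(x, fs, t0, window = c(0.05, 1.05),
                             theta_range = c(3, 8), nw = 3, ...) {
  i0 <- time_to_index(window[1] - t0, fs) + 1L
  len <- round((window[2] - window[1]) * fs)
  if (i0 < 1L || i0 + len - 1L > length(x))
    stop("trial does not cover the oscillation analysis window")
  est <- multitaper_psd(x[i0:(i0 + len - 1L)], fs, nw = nw)
  sel <- est$freqs >= 1e-9
  model <- fit_spectral_model(est$freqs[sel], est$psd[sel], ...)
  pk <- model$peaks
  pk <- pk[pk$center >= theta_range[1] & pk$center <= theta_range[2], , drop = FALSE]
  if (!nrow(pk)) return(NA_real_)
  max(pk$amplitude)
}

#' Per-contact TMS-minus-sham oscillation statistic
#'
#' Per-trial theta peak amplitudes averaged within condition and subtracted
#' (TMS minus sham). By default trials without a detected theta peak
#' contribute amplitude 0, so the statistic reflects both oscillation
#' prevalence and magnitude; `absent_as_zero = FALSE` instead averages over
#' peak-bearing trials only.
#'
#' @param epochs an `epoch_set` containing both conditions
#' @param channel channel index
#' @param min_trials minimum trials per condition (default 10)
#' @param absent_as_zero treat absent peaks as amplitude 0 (default TRUE)
#' @param ... passed to [trial_theta_peak()]
#' @return one-row data.frame: `contact`, `mean_theta_peak_tms`,
#'   `mean_theta_peak_sham`, `diff`, `n_tms`, `n_sham`, or `NULL` if the
#'   contact has too few trials
#' @export
contact_oscillation_stat <- function(epochs, channel, min_trials = 10,
                                     absent_as_zero = TRUE, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  tms <- which(epochs$condition == "tms")
  sham <- which(epochs$condition == "sham")
  if (length(tms) < min_trials || length(sham) < min_trials) return(NULL)
  amp <- function(idx) {
    a <- vapply(idx, function(i)
      trial_theta_peak(epochs$data[i, channel, ], epochs$fs, epochs$t0, ...),
      numeric(1))
    if (absent_as_zero) a[is.na(a)] <- 0
    if (all(is.na(a))) 0 else mean(a, na.rm = TRUE)
  }
  m_t <- amp(tms); m_s <- amp(sham)
  data.frame(contact = epochs$channel_names[channel],
             mean_theta_peak_tms = m_t, mean_theta_peak_sham = m_s,
             diff = m_t - m_s, n_tms = length(tms), n_sham = length(sham),
             stringsAsFactors = FALSE)
}

#' Oscillation statistics for every channel of an epoch set
#' @inheritParams contact_oscillation_stat
#' @param channels channel indices (default all)
#' @return data.frame, one row per contact (see
#'   [contact_oscillation_stat()])
#' @export
oscillation_stats <- function(epochs, channels = seq_len(dim(epochs$data)[2]),
                              min_trials = 10, absent_as_zero = TRUE, ...) {
  rows <- lapply(channels, function(c)
    contact_oscillation_stat(epochs, c, min_trials, absent_as_zero, ...))
  do.call(rbind, rows)
}

#' Region-level test of the oscillation statistic
#'
#' One-sample t of the per-contact TMS-minus-sham differences against zero.
#' @param diffs per-contact differences (>= 2)
#' @return list with `t`, `p`, `n`, `degenerate` (see [subregion_ttest()])
#' @export
region_oscillation_test <- function(diffs) subregion_ttest(diffs)

#' Correlation between power-based and oscillation-based region statistics
#'
#' Pearson correlation across regions between the spectral-power t
#' statistics and the oscillation-detection t statistics.
#' @param power_t,osc_t per-region statistics (>= 3 regions)
#' @return list with `r`, `p`, `df` (`n - 2`), `n`
#' @export
power_oscillation_correlation <- function(power_t, osc_t) {
  if (length(power_t) != length(osc_t)) stop("inputs must have equal length")
  keep <- is.finite(power_t) & is.finite(osc_t)
  n <- sum(keep)
  if (n < 3L) stop("need at least 3 regions")
  ct <- stats::cor.test(power_t[keep], osc_t[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = n - 2L, n = n)
}
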
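# Multitaper spectral estimation. The workhorse operates on a samples x
# series matrix so that trials (and channels) are processed with a single
# mvfft call per taper.

#' Multitaper power spectral density
#'
#' Averages direct spectral estimates over DPSS tapers, dropping tapers whose
#' in-band concentration falls below `min_concentration`.
#'
#' @param x numeric vector, or samples x series matrix (each column one
#'   segment; typically trials)
#' @param fs sampling rate in Hz
#' @param nw time-bandwidth product (default 4)
#' @param k number of tapers before the concentration screen
#' @param min_concentration tapers with concentration below this are excluded
#'   (default 0.9)
#' @return list with `freqs` (Hz, non-negative Fourier frequencies) and `psd`
#'   (frequencies x series matrix, density units x^2/Hz), plus `n_tapers` used
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 2 * nw - 1,
                           min_concentration = 0.9) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 8) stop("segment too short for multitaper estimation")
  dp <- dpss_tapers(n, nw = nw, k = k)
  keep <- dp$concentration >= min_concentration
  if (!any(keep)) keep[1] <- TRUE
  tap <- dp$tapers[, keep, drop = FALSE]
  nk <- ncol(tap)
  nf <- floor(n / 2) + 1L
  acc <- matrix(0, nf, ncol(x))
  for (j in seq_len(nk)) {
    F <- stats::mvfft(x * tap[, j])
    acc <- acc + (Mod(F[seq_len(nf), , drop = FALSE])^2)
  }
  # one-sided density scaling; tapers are unit-norm so 1/fs converts to density
  psd <- acc / (nk * fs)
  psd[-1, ] <- 2 * psd[-1, ]
  if (n %% 2 == 0) psd[nf, ] <- psd[nf, ] / 2
  list(freqs = (seq_len(nf) - 1L) * fs / n, psd = psd, n_tapers = nk)
}

#' Band-averaged log power from a multitaper PSD
#'
#' Log-transforms the PSD per frequency bin (natural log) and averages the
#' logs across bins inside `[f_lo, f_hi]`, matching the band-power order of
#' operations used throughout the pipeline.
#'
#' @inheritParams multitaper_psd
#' @param f_lo,f_hi band edges in Hz (inclusive)
#' @return numeric vector, one log-power value per series (column of `x`)
#' @export
mt_band_logpower <- function(x, fs, f_lo, f_hi, nw = 4,
                             min_concentration = 0.9) {
  est <- multitaper_psd(x, fs, nw = nw, min_concentration = min_concentration)
  sel <- est$freqs >= f_lo & est$freqs <= f_hi
  if (!any(sel)) stop(sprintf("no Fourier frequencies inside [%g, %g] Hz", f_lo, f_hi))
  lp <- log(pmax(est$psd[sel, , drop = FALSE], .Machine$double.eps))
  colMeans(lp)
}

#' Thomson harmonic F-test for a sinusoid at a fixed frequency
#'
#' Tests for a deterministic sinusoidal component at frequency `f0` embedded
#' in locally white background, using the regression of the taper
#' eigencoefficients on the tapers' DC responses.
#'
#' @param x numeric vector
#' @param fs sampling rate in Hz
#' @param f0 test frequency in Hz
#' @param nw time-bandwidth product
#' @return list with `F` statistic (df 2, 2K-2), `df2`, and the complex
#'   amplitude estimate `c` such that the fitted line component is
#'   `Re(2 * c * exp(i 2 pi f0 t))`
#' @export
harmonic_ftest <- function(x, fs, f0, nw = 4) {
  n <- length(x)
  dp <- dpss_tapers(n, nw = nw)
  tap <- dp$tapers
  K <- ncol(tap)
  t <- (seq_len(n) - 1L) / fs
  e <- exp(-2i * pi * f0 * t)
  y <- drop(crossprod(tap, x * e))        # eigencoefficients at f0
  H0 <- colSums(tap)                       # taper DC responses
  chat <- sum(y * H0) / sum(H0^2)
  resid <- y - chat * H0
  Fstat <- (K - 1) * Mod(chat)^2 * sum(H0^2) / sum(Mod(resid)^2)
  list(F = Fstat, df2 = 2 * (K - 1), c = chat)
}
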
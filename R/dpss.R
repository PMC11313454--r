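# Discrete prolate spheroidal (Slepian) sequences, computed from the
# classical symmetric tridiagonal eigenproblem (Percival & Walden 1993,
# sec. 8.3), with in-band energy concentrations from the sinc-kernel
# quadratic form. Results are cached per (n, nw, k) because the pipeline
# reuses a small set of window lengths heavily.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computes the first `k` Slepian tapers of length `n` for time-bandwidth
#' product `nw`, together with their spectral concentrations in the band
#' `[-W, W]`, `W = nw / n` (in cycles per sample).
#'
#' @param n window length in samples
#' @param nw time-bandwidth product (default 4)
#' @param k number of tapers (default `2 * nw - 1`)
#' @return list with `tapers` (an `n x k` matrix, columns unit-norm, sign
#'   fixed so that each taper's sum is non-negative) and `concentration`
#'   (length-`k` vector of in-band energy fractions, decreasing)
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  check_scalar(n, "n", lower = 8)
  check_scalar(nw, "nw", lower = 1)
  k <- as.integer(k)
  if (k < 1L || k > n) stop_param("k", "must be in [1, n]")
  key <- sprintf("n%d_nw%g_k%d", as.integer(n), nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])

  n <- as.integer(n)
  w <- nw / n
  t <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1])) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- diag_off
  A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit norm; fix sign so sum(taper) >= 0 (even orders), or first nonzero
  # lag-one slope positive (odd orders, whose sum is ~0)
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (sum((n - t) * tap[, j]) < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  # concentrations: lambda_j = v' S v with S_ij = sin(2 pi W (i-j)) / (pi (i-j))
  d <- outer(t, t, "-")
  S <- ifelse(d == 0, 2 * w, sin(2 * pi * w * d) / (pi * d))
  conc <- vapply(seq_len(k), function(j) drop(crossprod(tap[, j], S %*% tap[, j])),
                 numeric(1))
  out <- list(tapers = tap, concentration = conc)
  .dpss_cache[[key]] <- out
  out
}
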
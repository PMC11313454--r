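# Shared helpers. Conventions used package-wide: times in seconds, 0-based
# sample indexing in the time<->index maps, half-open windows [start, end).

#' Convert a time in seconds to a 0-based sample index
#' @param t time in seconds
#' @param fs sampling rate in Hz
#' @return integer 0-based index
#' @keywords internal
time_to_index <- function(t, fs) as.integer(round(t * fs))

#' Round half away from zero to a fixed number of decimals
#'
#' Base [round()] rounds half to even; reported percentages use conventional
#' half-up rounding.
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never perturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a finite numeric scalar")
  if (x < lower) stop_param(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_param(field, sprintf("must be <= %g", upper))
  invisible(x)
}
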
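# Contact-level TMS-vs-sham contrasts and hierarchical aggregation: pooled
# two-sample t per contact, intercept-only mixed models with subject random
# effects, Wald tests, and Benjamini-Hochberg FDR over timepoints.

#' Pooled-variance two-sample t statistic
#'
#' Classic two-sample t on baseline-corrected log powers (TMS vs sham).
#' Degenerate inputs with zero pooled variance yield `NaN` with a warning.
#'
#' @param power_tms,power_sham per-trial values (>= 2 each)
#' @return the t statistic (positive when TMS exceeds sham)
#' @export
contact_tstat <- function(power_tms, power_sham) {
  n1 <- length(power_tms); n2 <- length(power_sham)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 trials per condition")
  sp2 <- ((n1 - 1) * stats::var(power_tms) + (n2 - 1) * stats::var(power_sham)) /
    (n1 + n2 - 2)
  if (sp2 <= 0 || !is.finite(sp2)) {
    warning("zero pooled variance; t statistic undefined")
    return(NaN)
  }
  (mean(power_tms) - mean(power_sham)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' TMS-vs-sham t statistics for every channel and window of a band-power set
#'
#' @param bp a [band_power()] result (baseline-corrected values)
#' @return channels x windows matrix of t statistics
#' @export
power_tstats <- function(bp) {
  stopifnot(inherits(bp, "band_power"))
  tms <- bp$condition == "tms"
  sham <- bp$condition == "sham"
  d <- dim(bp$values)
  out <- matrix(NA_real_, d[2], d[3])
  for (c in seq_len(d[2])) for (w in seq_len(d[3]))
    out[c, w] <- contact_tstat(bp$values[tms, c, w], bp$values[sham, c, w])
  rownames(out) <- bp$channel_names
  colnames(out) <- sprintf("w%.2f", bp$window_starts)
  out
}

#' Average contact statistics into per-subject ROI means
#'
#' @param stats data.frame with columns `subject`, `roi`, `t` (and anything
#'   else, preserved by first value); `NaN`/`NA` t values are excluded and
#'   the contact count decremented
#' @return data.frame with `subject`, `roi`, `t` (mean over contacts),
#'   `n_contacts`
#' @export
roi_aggregate <- function(stats) {
  stopifnot(all(c("subject", "roi", "t") %in% names(stats)))
  stats <- stats[is.finite(stats$t), , drop = FALSE]
  if (!nrow(stats))
    return(data.frame(subject = character(), roi = character(),
                      t = numeric(), n_contacts = integer()))
  agg <- stats::aggregate(t ~ subject + roi, data = stats, FUN = mean)
  cnt <- stats::aggregate(t ~ subject + roi, data = stats, FUN = length)
  agg$n_contacts <- cnt$t
  agg
}

#' Intercept-only mixed model with subject random effects
#'
#' Fits `value ~ 1 + (1 | subject)` by REML and tests the intercept against
#' zero with a Wald z test. On non-convergence the fit falls back to a
#' one-sample t over subject means, flagged via `method`.
#'
#' @param values contact-level statistics (one per contact)
#' @param subjects subject id per value
#' @param min_subjects minimum distinct subjects required (default 5)
#' @return one-row data.frame: `intercept`, `se`, `wald_z`, `p_value`,
#'   `ci_lo`, `ci_hi` (95%), `n_subjects`, `n_contacts`, `method`
#' @export
lmm_intercept <- function(values, subjects, min_subjects = 5) {
  keep <- is.finite(values)
  values <- values[keep]; subjects <- as.character(subjects)[keep]
  ns <- length(unique(subjects))
  if (ns < min_subjects)
    stop(sprintf("only %d subject(s); at least %d required", ns, min_subjects))
  df <- data.frame(value = values, subject = subjects)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 1 + (1 | subject), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- unname(lme4::fixef(fit)[1])
    se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
    method <- "lmm_wald"
  } else {
    sm <- tapply(df$value, df$subject, mean)
    est <- mean(sm)
    se <- stats::sd(sm) / sqrt(length(sm))
    method <- "subject_t_fallback"
  }
  z <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  data.frame(intercept = est, se = se, wald_z = z, p_value = p,
             ci_lo = est - stats::qnorm(0.975) * se,
             ci_hi = est + stats::qnorm(0.975) * se,
             n_subjects = ns, n_contacts = length(values),
             method = method, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up control of the false discovery rate; returns adjusted q-values
#' and the rejection mask at level `alpha`.
#' @param p_values p-values in `[0, 1]`
#' @param alpha FDR level (default 0.05)
#' @return list with `q_values` and logical `reject`
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(q_values = numeric(), reject = logical()))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_param("p_values", "must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= alpha)
}

#' One-sample t test of contact statistics against zero
#'
#' Used for subregions where mixed models fail to converge on few contacts,
#' and for oscillation-statistic region tests. A zero-variance input with a
#' nonzero mean is degenerate: it returns `p = 0` with `degenerate = TRUE`.
#'
#' @param values contact-level statistics (>= 2 finite values)
#' @return list with `t`, `p`, `df`, `n`, `degenerate`
#' @export
subregion_ttest <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 contacts")
  s <- stats::sd(values)
  if (s == 0) {
    m <- mean(values)
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, n = n, degenerate = TRUE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(values)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       n = n, degenerate = FALSE)
}

#' Pixelwise significance of time-frequency t maps
#'
#' Contact t maps are averaged within subject, each pixel tested against
#' zero with a one-sample t across subjects, and p-values FDR-corrected over
#' the full time-frequency grid.
#'
#' @param tmaps contacts x pixels matrix of t statistics (flatten the
#'   time-frequency grid to columns)
#' @param subjects subject id per contact (row)
#' @param alpha FDR level
#' @param min_subjects minimum distinct subjects (default 5)
#' @return list with `mask` (logical per pixel), `p_values`, `q_values`,
#'   `mean_t` (subject-mean average per pixel)
#' @export
tfr_pixel_test <- function(tmaps, subjects, alpha = 0.05, min_subjects = 5) {
  subjects <- as.character(subjects)
  us <- unique(subjects)
  if (length(us) < min_subjects)
    stop(sprintf("only %d subject(s); at least %d required", length(us), min_subjects))
  sm <- t(vapply(us, function(s)
    colMeans(tmaps[subjects == s, , drop = FALSE]), numeric(ncol(tmaps))))
  p <- apply(sm, 2, function(v) {
    if (stats::sd(v) == 0) return(if (mean(v) == 0) 1 else 0)
    stats::t.test(v)$p.value
  })
  fdr <- fdr_correct(p, alpha)
  list(mask = fdr$reject, p_values = p, q_values = fdr$q_values,
       mean_t = colMeans(sm))
}

#' Early-versus-late session adaptation contrast
#'
#' Splits each contact's active trials into the first and last `first_n`
#' (time order), computes the TMS-vs-sham t statistic separately for the
#' early and late subsets (sham trials split the same way), averages over
#' windows, and tests the per-contact late-minus-early difference against
#' zero with a one-sample t.
#'
#' @param bp a [band_power()] result (trials in session order)
#' @param first_n,last_n trial counts for the early and late subsets
#' @return list with `t`, `p`, `n` (contacts contributing) and the
#'   per-contact `diffs`; contacts (or the whole call) with too few trials
#'   are skipped
#' @export
adaptation_contrast <- function(bp, first_n = 25, last_n = 25) {
  stopifnot(inherits(bp, "band_power"))
  tms <- which(bp$condition == "tms")
  sham <- which(bp$condition == "sham")
  if (length(tms) < first_n + last_n || length(sham) < first_n + last_n)
    stop(sprintf("session has too few trials for a %d + %d split", first_n, last_n))
  early_t <- tms[seq_len(first_n)]
  late_t <- tms[(length(tms) - last_n + 1L):length(tms)]
  early_s <- sham[seq_len(first_n)]
  late_s <- sham[(length(sham) - last_n + 1L):length(sham)]
  d <- dim(bp$values)
  diffs <- rep(NA_real_, d[2])
  for (c in seq_len(d[2])) {
    tw <- vapply(seq_len(d[3]), function(w) {
      te <- contact_tstat(bp$values[early_t, c, w], bp$values[early_s, c, w])
      tl <- contact_tstat(bp$values[late_t, c, w], bp$values[late_s, c, w])
      tl - te
    }, numeric(1))
    diffs[c] <- mean(tw, na.rm = TRUE)
  }
  res <- subregion_ttest(diffs)
  list(t = res$t, p = res$p, n = res$n, diffs = diffs)
}

#' Group-level effects per ROI, band and window with FDR over windows
#'
#' Runs [lmm_intercept()] for every window of every ROI and applies
#' Benjamini-Hochberg correction across the windows within each ROI (the
#' FDR family is timepoints, not regions or bands). ROIs sampled in fewer
#' than `min_subjects` subjects are omitted.
#'
#' @param contact_stats data.frame with columns `subject`, `contact`, `roi`,
#'   `window_start`, `t`
#' @param alpha FDR level (default 0.05)
#' @param min_subjects minimum subjects per ROI (default 5)
#' @return data.frame, one row per ROI x window: intercept, Wald z, p, q,
#'   CI, counts
#' @export
group_effects <- function(contact_stats, alpha = 0.05, min_subjects = 5) {
  needed <- c("subject", "roi", "window_start", "t")
  stopifnot(all(needed %in% names(contact_stats)))
  out <- list()
  for (roi in unique(contact_stats$roi)) {
    sub <- contact_stats[contact_stats$roi == roi, , drop = FALSE]
    if (length(unique(sub$subject)) < min_subjects) next
    rows <- lapply(sort(unique(sub$window_start)), function(w) {
      sw <- sub[sub$window_start == w, , drop = FALSE]
      r <- lmm_intercept(sw$t, sw$subject, min_subjects = min_subjects)
      cbind(data.frame(roi = roi, window_start = w), r)
    })
    tab <- do.call(rbind, rows)
    fdr <- fdr_correct(tab$p_value, alpha)
    tab$q_value <- fdr$q_values
    tab$significant <- fdr$reject
    out[[roi]] <- tab
  }
  if (!length(out))
    stop(sprintf("no ROI was sampled in at least %d subjects", min_subjects))
  do.call(rbind, c(out, make.row.names = FALSE))
}
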
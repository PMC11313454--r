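# Contact-level contrasts, mixed-model aggregation, FDR, adaptation.

test_that("the pooled two-sample t matches hand computation", {
  expect_equal(contact_tstat(c(1, 2, 3), c(0, 1, 2)), 1.224745,
               tolerance = 1e-6)
  x <- rnorm(20)
  expect_equal(contact_tstat(x, x), 0)
  expect_warning(t0 <- contact_tstat(rep(1, 5), rep(1, 5)), "variance")
  expect_true(is.nan(t0))
  expect_error(contact_tstat(1, c(1, 2)), "at least 2")
})

test_that("ROI aggregation averages within subject and drops NaN contacts", {
  df <- data.frame(subject = c("a", "a", "a", "b"),
                   roi = "frontal", t = c(1, 3, NaN, 2))
  agg <- roi_aggregate(df)
  expect_equal(agg$t[agg$subject == "a"], 2)
  expect_equal(agg$n_contacts[agg$subject == "a"], 2)
  expect_equal(agg$t[agg$subject == "b"], 2)
})

test_that("the intercept-only mixed model behaves like a one-sample test", {
  subj <- sprintf("s%02d", 1:20)
  expect_error(lmm_intercept(rnorm(4), sprintf("s%d", 1:4)), "at least 5")

  z <- lmm_intercept(rep(0, 10), sprintf("s%d", 1:10))
  expect_equal(z$intercept, 0)
  expect_equal(z$p_value, 1)

  # one value per subject: Wald z approximates the one-sample t
  set.seed(25)
  v <- rnorm(20, mean = 0.6)
  fit <- lmm_intercept(v, subj)
  tt <- t.test(v)
  expect_equal(fit$wald_z, unname(tt$statistic), tolerance = 0.1 * abs(tt$statistic))
  expect_true(fit$ci_lo <= fit$intercept && fit$intercept <= fit$ci_hi)

  # intercept sign always matches the grand-mean sign
  for (seed in 1:5) {
    set.seed(seed)
    vv <- rnorm(30, mean = sample(c(-1, 1), 1) * 0.5)
    ss <- rep(sprintf("s%d", 1:6), each = 5)
    f <- lmm_intercept(vv, ss)
    expect_equal(sign(f$intercept), sign(mean(vv)))
  }
})

test_that("the mixed-model SE shrinks as contacts accumulate", {
  set.seed(26)
  mk <- function(k) {
    v <- rnorm(6 * k, 0.3)
    lmm_intercept(v, rep(sprintf("s%d", 1:6), each = k))$se
  }
  se_small <- mean(replicate(10, mk(3)))
  se_big <- mean(replicate(10, mk(30)))
  expect_lt(se_big, se_small)
})

test_that("BH correction matches the enumerated step-up oracle", {
  f <- fdr_correct(c(0.01, 0.02, 0.04, 0.2), alpha = 0.05)
  expect_identical(f$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$q_values, c(0.04, 0.04, 0.05333333, 0.2), tolerance = 1e-6)

  expect_true(all(fdr_correct(rep(0.01, 10))$reject))
  expect_false(any(fdr_correct(rep(1, 10))$reject))
  expect_identical(fdr_correct(numeric())$reject, logical())

  set.seed(27)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    f1 <- fdr_correct(p)
    f2 <- bh_oracle(p)
    expect_identical(f1$reject, f2$reject)
    expect_equal(f1$q_values, f2$q, tolerance = 1e-12)
    # q monotone nondecreasing in sorted p
    expect_true(all(diff(f1$q_values[order(p)]) >= -1e-12))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("one-sample subregion tests match hand computation and guard degeneracy", {
  r <- subregion_ttest(c(0.5, 1.0, 1.5))
  expect_equal(r$t, 3.464102, tolerance = 1e-6)
  expect_equal(subregion_ttest(c(-1, 1))$t, 0)
  d <- subregion_ttest(c(1, 1, 1, 1))
  expect_true(d$degenerate)
  expect_lt(d$p, 0.01)
  expect_error(subregion_ttest(1), "at least 2")
})

test_that("pixel tests flag only truly non-null time-frequency pixels", {
  set.seed(28)
  n_sub <- 10; n_pix <- 50
  tmaps <- matrix(rnorm(3 * n_sub * n_pix, 0, 1), 3 * n_sub)
  subj <- rep(sprintf("s%d", 1:n_sub), each = 3)
  tmaps[, 17] <- tmaps[, 17] + 5        # one strongly affected pixel
  r <- tfr_pixel_test(tmaps, subj)
  expect_true(r$mask[17])
  expect_lt(sum(r$mask[-17]), 3)
  expect_true(all(abs(r$mean_t[r$mask]) > 0))

  zero <- tfr_pixel_test(matrix(0, 2 * n_sub, 5), rep(sprintf("s%d", 1:n_sub), 2))
  expect_false(any(zero$mask))
})

test_that("the adaptation contrast detects amplitude drift across a session", {
  mkbp <- function(drift, subj) {
    cfg <- synth_config(n_subjects = subj, contacts_per_region = 5,
                        region_profiles = list(
                          region_profile("ind", induced_amp = 12,
                                         sham_click_amp = 0)),
                        n_tms_trials = 100, n_sham_trials = 100,
                        artifact_amplitude = 0, line_noise_amplitude = 0,
                        amplitude_drift = drift, fs_raw = 500, rng_seed = 29)
    ds <- generate_dataset(cfg)
    lapply(names(ds$recordings), function(s) {
      ch <- ds$channels[ds$channels$subject == s, ]
      ev <- ds$events[ds$events$subject == s, ]
      rr <- rereference(ds$recordings[[s]], ch)
      band_power(epoch_recording(rr$recording, ev), band_spec("theta"))
    })
  }
  # pool the per-contact late-minus-early differences across subjects
  bps <- mkbp(-0.8, 3)
  diffs <- unlist(lapply(bps, function(b)
    adaptation_contrast(b, first_n = 25, last_n = 25)$diffs))
  res <- subregion_ttest(diffs)
  expect_lt(res$t, 0)
  expect_lt(res$p, 0.05)
  expect_error(adaptation_contrast(bps[[1]], first_n = 60, last_n = 60),
               "too few trials")
})

test_that("group effects report per-window mixed models with within-ROI FDR", {
  set.seed(30)
  df <- expand.grid(subject = sprintf("s%d", 1:6), contact = 1:4,
                    window_start = power_window_starts())
  df$roi <- "frontal"
  df$t <- rnorm(nrow(df)) + ifelse(df$window_start < 0.1, 2, 0)
  g <- group_effects(df)
  expect_identical(nrow(g), 9L)
  expect_true(g$significant[g$window_start == 0.05])
  expect_true(all(g$q_value >= g$p_value - 1e-12))
  expect_true(all(g$n_subjects == 6))
  # an under-sampled ROI is omitted (and alone it is an error)
  df2 <- df[df$subject %in% sprintf("s%d", 1:3), ]
  expect_error(group_effects(df2), "at least 5")
})
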
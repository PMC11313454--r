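# Inter-trial phase locking, trial matching, mirror buffering, ΔIPL.

test_that("the resultant-vector statistic matches closed forms", {
  expect_equal(phase_locking_value(rep(1.3, 50)), 1, tolerance = 1e-12)
  expect_equal(phase_locking_value(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  expect_equal(phase_locking_value(c(0, pi / 3)), cos(pi / 6),
               tolerance = 1e-12)
})

test_that("phase locking is exactly invariant to a common phase offset", {
  set.seed(18)
  ph <- runif(40, 0, 2 * pi)
  for (off in c(0.1, 1, pi, 5))
    expect_equal(phase_locking_value(ph + off), phase_locking_value(ph),
                 tolerance = 1e-12)
})

test_that("uniform-phase IPL follows the sqrt(pi)/2 n^-1/2 small-sample bias", {
  set.seed(19)
  for (n in c(16, 64, 256)) {
    est <- mean(replicate(400, phase_locking_value(runif(n, 0, 2 * pi))))
    expect_equal(est, sqrt(pi) / 2 / sqrt(n), tolerance = 0.2)
  }
})

test_that("trial matching subsamples both conditions to the smaller count", {
  set.seed(20)
  m <- match_trial_counts(150, 300)
  expect_identical(length(m$tms), 150L)
  expect_identical(length(m$sham), 150L)
  expect_false(anyDuplicated(m$sham) > 0)
  m2 <- match_trial_counts(50, 50)
  expect_identical(length(m2$tms), 50L)
  set.seed(77); a <- match_trial_counts(30, 80)
  set.seed(77); b <- match_trial_counts(30, 80)
  expect_identical(a, b)
  expect_error(match_trial_counts(1, 50), "n_tms")
})

test_that("mirror buffering reverses the edges and round-trips", {
  expect_identical(mirror_buffer(c(1, 2, 3, 4), 2),
                   c(2, 1, 1, 2, 3, 4, 4, 3))
  x <- sin(1:100)
  p <- mirror_buffer(x, 30)
  expect_identical(p[31:130], x)                  # pad-then-clip identity
  expect_equal(p[30], p[31], tolerance = 1e-12)   # continuous at the joins
  expect_equal(p[130], p[131], tolerance = 1e-12)
  expect_error(mirror_buffer(x, 200), "shorter")
})

test_that("identical trials give IPL 1 everywhere; one trial is an error", {
  fs <- 500
  w <- sin(2 * pi * 5 * (0:1249) / fs) + 0.3 * sin(2 * pi * 3.3 * (0:1249) / fs)
  ep <- make_epochs(function(i) w, n_trials = 12)
  ipl <- inter_trial_phase_locking(ep)
  expect_equal(min(ipl$ipl), 1, tolerance = 1e-9)
  ep1 <- make_epochs(function(i) w, n_trials = 1)
  expect_error(inter_trial_phase_locking(ep1), "fewer than 2")
})

test_that("IPL is invariant to rotating every trial by a common phase", {
  # shifting all trials by the same lag rotates every coefficient phase by
  # the same angle, which must leave the resultant length unchanged
  fs <- 500
  set.seed(22)
  base <- function(i) sin(2 * pi * 5 * ((0:1399) / fs) + i) + rnorm(1400)
  trials <- lapply(1:10, function(i) base(i))
  mk <- function(lag) make_epochs(function(i) trials[[i]][(1 + lag):(1250 + lag)],
                                  n_trials = 10)
  i0 <- inter_trial_phase_locking(mk(0), freqs = 5)
  i1 <- inter_trial_phase_locking(mk(25), freqs = 5)   # 50 ms common shift
  mid <- 300:900
  # the shifted epochs see the original data 25 samples later
  expect_equal(i1$ipl[1, 1, mid], i0$ipl[1, 1, mid + 25], tolerance = 0.02)
})

test_that("ΔIPL is zero when conditions are identical and errors on grid mismatch", {
  fs <- 500
  set.seed(23)
  ep <- make_epochs(function(i) rnorm(1250), n_trials = 8)
  ia <- inter_trial_phase_locking(ep)
  d <- delta_ipl(ia, ia)
  expect_equal(max(abs(d$delta)), 0)
  ib <- ia
  ib$freqs <- 4:9
  expect_error(delta_ipl(ia, ib), "grids")
})

test_that("evoked regions show early positive ΔIPL; induced regions do not", {
  fs <- 500
  prof_ev <- region_profile("ev", evoked_amp = 10, evoked_freq = 5,
                            evoked_decay = 0.3, sham_click_amp = 0)
  prof_ind <- region_profile("ind", induced_amp = 12, induced_freq = 6,
                             sham_click_amp = 0)
  set.seed(24)
  mk <- function(prof) {
    cond <- rep(c("tms", "sham"), each = 60)
    make_epochs(function(i) synth_trial(prof, cond[i], fs = fs),
                n_trials = 120, condition = cond)
  }
  d_ev <- compute_delta_ipl(mk(prof_ev))
  d_ind <- compute_delta_ipl(mk(prof_ind))
  early <- d_ev$times >= 0.1 & d_ev$times < 0.6
  late <- d_ev$times >= 1.3 & d_ev$times < 1.8
  ev_early <- max(apply(d_ev$delta[1, , early], 2, mean))
  expect_gt(ev_early, 0.3)
  # decays toward zero late in the inter-stimulation period
  expect_lt(mean(d_ev$delta[1, , late]), 0.5 * ev_early)
  # induced bursts carry no phase locking despite their power
  expect_lt(max(abs(apply(d_ind$delta[1, , early], 2, mean))), 0.15)
})
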
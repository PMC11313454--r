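# Re-referencing, artifact interpolation, line-noise removal, downsampling,
# epoching.

rec_of <- function(mat, fs = 500, names = sprintf("c%d", seq_len(nrow(mat))))
  continuous_recording(mat, fs, names)

test_that("bipolar re-referencing takes adjacent differences within shaft", {
  x1 <- sin(seq(0, 10, length.out = 1000)); x2 <- cos(seq(0, 10, length.out = 1000))
  rec <- rec_of(rbind(x1, x2))
  ch <- rbind(ch_row("c1", idx = 1), ch_row("c2", idx = 2))
  out <- rereference(rec, ch)
  expect_identical(nrow(out$recording$data), 1L)
  expect_equal(out$recording$data[1, ], x1 - x2)
  expect_identical(out$channels$name, "c1-c2")

  # 4-contact shaft with constant levels (1, 2, 4, 8) -> (-1, -2, -4)
  rec4 <- rec_of(matrix(c(1, 2, 4, 8), 4, 1000))
  ch4 <- do.call(rbind, lapply(1:4, function(i) ch_row(paste0("c", i), idx = i)))
  out4 <- rereference(rec4, ch4)
  expect_equal(out4$recording$data[, 1], c(-1, -2, -4))
  expect_equal(apply(out4$recording$data, 1, sd), rep(0, 3))
})

test_that("grid channels sharing one signal are zeroed by the common average", {
  s <- rnorm(500)
  rec <- rec_of(rbind(s, s, s))
  ch <- do.call(rbind, lapply(1:3, function(i)
    ch_row(paste0("c", i), montage = "grid", idx = i)))
  out <- rereference(rec, ch)
  expect_equal(max(abs(out$recording$data)), 0)
})

test_that("excluded channels are left out of the common average and pairing", {
  s <- rnorm(500)
  rec <- rec_of(rbind(s, s, 100 + s))
  ch <- rbind(ch_row("c1", montage = "grid", idx = 1),
              ch_row("c2", montage = "grid", idx = 2),
              ch_row("c3", montage = "grid", idx = 3,
                     status = "excluded", reason = "saturation"))
  out <- rereference(rec, ch)
  # average over the two good channels only -> outputs zero, excluded gone
  expect_identical(nrow(out$recording$data), 2L)
  expect_equal(max(abs(out$recording$data)), 0)

  # a depth shaft reduced to one usable contact is dropped with a warning
  ch2 <- rbind(ch_row("c1", idx = 1),
               ch_row("c2", idx = 2, status = "excluded", reason = "noise"),
               ch_row("c3", shaft = "B", idx = 1),
               ch_row("c4", shaft = "B", idx = 2))
  rec2 <- rec_of(matrix(rnorm(2000), 4))
  expect_warning(out2 <- rereference(rec2, ch2), "single usable contact")
  expect_identical(out2$channels$name, "c3-c4")
})

test_that("unknown montage types are rejected", {
  rec <- rec_of(matrix(rnorm(500), 1))
  ch <- ch_row("c1", montage = "depth")
  ch$montage_type <- "scalp"
  expect_error(rereference(rec, ch), "montage")
})

test_that("artifact interpolation reproduces the reverse-taper-sum rule", {
  fs <- 1000
  n <- 400
  onset <- 0.2
  set.seed(9)
  x <- rnorm(n)
  y <- interpolate_artifact(x, fs, onset)
  # brute-force oracle over the 50 ms replacement window
  a <- round((onset - 0.025) * fs) + 1L
  b <- round((onset + 0.025) * fs)
  L <- b - a + 1L
  pre <- x[(a - 50):(a - 1)]
  post <- x[(b + 1):(b + 50)]
  for (j in 0:(L - 1)) {
    wd <- 1 - j / (L - 1)
    expect_equal(y[a + j], rev(pre)[j + 1] * wd + rev(post)[j + 1] * (1 - wd),
                 tolerance = 1e-12)
  }
  expect_identical(y[-(a:b)], x[-(a:b)])     # untouched outside
})

test_that("interpolation is exact on degenerate traces and idempotent", {
  fs <- 500
  z <- numeric(1000)
  expect_equal(interpolate_artifact(z, fs, 1), z)
  cst <- rep(3.7, 1000)
  expect_equal(interpolate_artifact(cst, fs, 1), cst)
  set.seed(10)
  x <- rnorm(1000)
  y1 <- interpolate_artifact(x, fs, 1)
  y2 <- interpolate_artifact(y1, fs, 1)
  expect_identical(y1, y2)
  expect_error(interpolate_artifact(x, fs, 0.03), "flanking")
})

test_that("line-noise removal attenuates significant harmonics only", {
  set.seed(11)
  fs <- 500
  n <- 4 * fs
  t <- (0:(n - 1)) / fs
  noise <- rnorm(n)
  amp <- sqrt(20)                  # A^2/2 = 10x the unit noise variance
  x <- noise + amp * cos(2 * pi * 60 * t + 0.3)
  y <- remove_line_noise(x, fs)
  pg <- function(v) abs(fft(v))^2 / length(v)
  P <- pg(y)
  f <- (0:(n - 1)) * fs / n
  i60 <- which.min(abs(f - 60))
  neigh <- P[c(i60 - 5, i60 - 4, i60 + 4, i60 + 5)]
  expect_lt(10 * log10(P[i60] / mean(neigh)), 3)

  # pure white noise passes through essentially unchanged
  w <- rnorm(n)
  expect_lt(max(abs(remove_line_noise(w, fs) - w)), 0.05 * sd(w))

  # both 60 and 120 Hz components attenuated by at least 20 dB
  x2 <- rnorm(n) + 2 * cos(2 * pi * 60 * t) + 2 * sin(2 * pi * 120 * t)
  y2 <- remove_line_noise(x2, fs)
  P0 <- pg(x2); P1 <- pg(y2)
  for (fh in c(60, 120)) {
    i <- which.min(abs(f - fh))
    expect_gt(10 * log10(P0[i] / P1[i]), 20)
  }
})

test_that("downsampling preserves passband tones and kills aliases", {
  fs <- 8000
  t <- (0:(fs * 2 - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  y <- downsample(tone, 500, fs = fs)
  expect_equal(length(y), 1000)
  mid <- y[200:800]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)

  cst <- downsample(rep(2.5, fs), 500, fs = fs)
  expect_equal(cst[100:300], rep(2.5, 201), tolerance = 1e-6)

  # 300 Hz sits above the 250 Hz target Nyquist: >= 40 dB down
  alias <- sin(2 * pi * 300 * t)
  ya <- downsample(alias, 500, fs = fs)
  expect_lt(20 * log10(max(abs(ya[200:800]))), -40)

  expect_error(downsample(tone, 16000, fs = fs), "exceeds")
})

test_that("epoching returns one trial per event with exact alignment", {
  fs <- 500
  n <- fs * 120
  onsets <- seq(5, 103, by = 2)[1:50]
  x <- numeric(n)
  x[round(onsets * fs) + 1L] <- 1          # delta at each onset
  rec <- continuous_recording(matrix(x, 1), fs, "c1")
  ev <- data.frame(onset_s = onsets,
                   condition = rep(c("tms", "sham"), 25),
                   target = "dlpfc", subject = "s1", session = "ses-01")
  ep <- epoch_recording(rec, ev)
  expect_identical(dim(ep$data), c(50L, 1L, 1250L))
  # onset (t = 0) is 0-based sample 250 of each trial
  expect_true(all(ep$data[, 1, 251] == 1))
  expect_true(all(ep$data[, 1, -251] == 0))
  expect_identical(ep$condition, ev$condition)

  # event too close to the start is dropped with a warning
  ev2 <- rbind(data.frame(onset_s = 0.1, condition = "tms", target = "dlpfc",
                          subject = "s1", session = "ses-01"), ev)
  expect_warning(ep2 <- epoch_recording(rec, ev2), "dropped")
  expect_identical(dim(ep2$data)[1], 50L)
})

test_that("re-referencing commutes with epoching for bipolar montages", {
  set.seed(12)
  fs <- 500
  rec <- rec_of(matrix(rnorm(3 * fs * 30), 3), fs)
  ch <- do.call(rbind, lapply(1:3, function(i) ch_row(paste0("c", i), idx = i)))
  ev <- data.frame(onset_s = c(5, 7, 9), condition = c("tms", "sham", "tms"),
                   target = "dlpfc", subject = "s1", session = "ses-01")
  a <- epoch_recording(rereference(rec, ch)$recording, ev)
  b <- epoch_recording(rec, ev)
  manual <- b$data[, 1, , drop = FALSE] - b$data[, 2, , drop = FALSE]
  expect_equal(a$data[, 1, ], manual[, 1, ], tolerance = 1e-12)
})
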
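test_that("the low-pass filter has unit DC gain and rejects bad input", {
  x <- rep(3.7, 200)
  expect_equal(butterworth_lowpass(x, 100, 6), x, tolerance = 1e-8)
  expect_error(butterworth_lowpass(c(x, NA), 100, 6), "NA")
  expect_error(butterworth_lowpass(x, 100, 60), "Nyquist")
})

test_that("stop-band and cutoff attenuation match the Butterworth magnitude", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  # 50 Hz sinusoid through a 6 Hz cutoff: two passes of |H|^2 at w/wc = 50/6
  x50 <- sin(2 * pi * 50 * t)
  y50 <- butterworth_lowpass(x50, fs, 6)
  mid <- seq(500, 1500)
  gain_expected <- 1 / (1 + (50 / 6)^(2 * 4))     # order-4 magnitude, squared
  expect_lt(max(abs(y50[mid])), 10 * gain_expected + 1e-6)
  # at the cutoff the two passes give ~0.5 amplitude
  xc <- sin(2 * pi * 6 * t)
  yc <- butterworth_lowpass(xc, fs, 6)
  expect_equal(max(abs(yc[mid])), 0.5, tolerance = 0.02)
})

test_that("filtering is ~idempotent on band-limited signals", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + 0.5 * cos(2 * pi * 0.5 * t)
  y1 <- butterworth_lowpass(x, fs, 6)
  y2 <- butterworth_lowpass(y1, fs, 6)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(y2 - y1) / rms(y1), 0.01)
})

test_that("foot strikes are detected at pulse rising edges", {
  fs <- 1000
  fz <- rep(0, 5000)
  starts <- c(500, 1500, 2500, 3500)
  for (s in starts) fz[s:(s + 600)] <- 400
  fz_other <- rep(0, 5000)
  for (s in starts + 500) fz_other[s:(s + 400)] <- 400
  ev <- detect_foot_strikes(fz, fz_other, fs, threshold_n = 20)
  expect_equal(sum(ev$leg == "fast"), 4)
  expect_equal(ev$time[ev$leg == "fast"], (starts - 1) / fs)
  expect_true(all(ev$leg[-1] != ev$leg[-nrow(ev)]))
})

test_that("all-zero force raises an error naming the belt", {
  expect_error(detect_foot_strikes(rep(0, 1000), rep(0, 1000), 1000),
               "fast belt")
})

test_that("detection is invariant to sub-threshold noise", {
  fs <- 1000
  fz <- rep(0, 5000)
  for (s in c(500, 1500, 2500)) fz[s:(s + 600)] <- 400
  fz_slow <- rep(0, 5000)
  for (s in c(1000, 2000, 3000)) fz_slow[s:(s + 600)] <- 400
  set.seed(4)
  noisy <- pmax(fz + runif(5000, 0, 9), 0)     # below threshold/2
  ev1 <- detect_foot_strikes(fz, fz_slow, fs)
  ev2 <- detect_foot_strikes(noisy, fz_slow, fs)
  expect_equal(ev1$time[ev1$leg == "fast"], ev2$time[ev2$leg == "fast"],
               tolerance = 1e-6)
})

test_that("detected strikes match generator truth within 10 ms", {
  fx <- fixture_trial(n = 20L)
  pr <- process_trial(fx$trial)
  ev <- pr$events
  tru <- fx$trial$events
  m <- min(nrow(ev), nrow(tru))
  expect_lt(max(abs(ev$time[seq_len(m)] - tru$time[seq_len(m)])), 0.010)
  expect_equal(ev$leg[seq_len(m)], tru$leg[seq_len(m)])
})

test_that("strides tile the interval between ipsilateral strikes", {
  ev <- data.frame(time = c(0.0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0),
                   leg = rep(c("fast", "slow"), length.out = 7))
  seg <- segment_strides(ev, "fast")
  expect_equal(nrow(seg$strides), 3)
  expect_equal(seg$strides$start[-1], seg$strides$end[-3])
  expect_equal(seg$strides$duration_s, rep(1, 3))
  # each stride contains exactly two steps for alternating strikes
  expect_equal(unname(table(seg$steps$stride)), rep(2L, 3L),
               ignore_attr = TRUE)
  expect_equal(nrow(seg$steps), 2 * nrow(seg$strides))
  expect_error(segment_strides(ev[ev$leg == "slow", ][1, ], "slow"),
               "at least 2")
})

test_that("stride counts on synthetic trials match generator truth", {
  fx <- fixture_trial(n = 15L)
  pr <- process_trial(fx$trial)
  expect_equal(nrow(pr$strides), 15 - 1)   # n fast strikes -> n-1 strides
})
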
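test_that("step length asymmetry arithmetic and antisymmetry", {
  expect_equal(sla(0.5, 0.5), 0)
  expect_equal(sla(0.6, 0.4), 0.2)
  for (i in 1:20) {
    f <- runif(1, 0.2, 0.9); s <- runif(1, 0.2, 0.9)
    expect_equal(sla(f, s), -sla(s, f))
    expect_true(abs(sla(f, s)) < 1)
    if (f != s) expect_true(sla(f, s) != 0)
  }
  expect_error(sla(0, 0), "positive")
})

test_that("step length is the AP ankle separation at strike", {
  mk <- data.frame(time_s = seq(0, 1, by = 0.01))
  mk$ANK_L_x <- 0.3
  mk$ANK_R_x <- -0.3
  ev <- data.frame(time = 0.5, leg = "fast")
  st <- step_length_at_strike(mk, rbind(ev, data.frame(time = 0.9,
                                                       leg = "slow")),
                              fast_side = "left")
  expect_equal(st$step_length_fast_m, 0.6)
  expect_equal(st$step_length_slow_m, 0.6)
  mk$ANK_R_x <- 0.3
  st0 <- step_length_at_strike(mk, data.frame(time = c(0.4, 0.6),
                                              leg = c("fast", "slow")),
                               "left")
  expect_equal(st0$step_length_fast_m, 0)
  expect_error(step_length_at_strike(mk, data.frame(time = 2, leg = "fast"),
                                     "left"), "span")
})

test_that("COM kinematics: constant body-weight support gives zero motion", {
  tt <- seq(0, 2, by = 0.01)
  forces <- data.frame(time_s = tt, fx = 0, fy = 0, fz = 70 * 9.81)
  strides <- data.frame(stride = 1:2, start = c(0, 1), end = c(1, 2))
  com <- com_kinematics(forces, 70, strides)
  expect_true(all(abs(com$az) < 1e-12))
  expect_true(all(abs(com$vz) < 1e-12))
})

test_that("COM velocity of a sinusoidal vertical force matches closed form", {
  m <- 70; G <- 9.81; A <- 100; Tp <- 1
  tt <- seq(0, 1, by = 0.001)
  forces <- data.frame(time_s = tt, fx = 0, fy = 0,
                       fz = m * G + A * sin(2 * pi * tt / Tp))
  strides <- data.frame(stride = 1, start = 0, end = 1 + 1e-9)
  com <- com_kinematics(forces, m, strides)
  expected <- -(A / m) * (Tp / (2 * pi)) * cos(2 * pi * tt / Tp)
  expected <- expected - mean(expected)
  expect_equal(com$vz, expected, tolerance = 1e-4)
  expect_lt(abs(mean(com$vz)), 1e-12)      # stride-mean zero by construction
})

test_that("per-stride COM vertical excursion is periodic on synthetic trials", {
  fx <- fixture_trial(n = 20L)
  pr <- process_trial(fx$trial)
  com <- pr$com
  for (k in unique(com$stride)[5:10]) {
    d <- com[com$stride == k, ]
    z <- cumsum(c(0, diff(d$time_s) * (d$vz[-1] + d$vz[-nrow(d)]) / 2))
    expect_lt(abs(z[length(z)] - z[1]), 0.005)
  }
})

test_that("leg power follows the individual-limbs sign conventions", {
  n <- 11
  v0 <- data.frame(vx = rep(0, n), vy = 0, vz = 0)
  zero <- data.frame(fx = rep(0, n), fy = 0, fz = 0)
  expect_equal(leg_power(zero, v0, 1), rep(0, n))
  vert <- data.frame(fx = rep(0, n), fy = 0, fz = 700)
  expect_equal(leg_power(vert, v0, 1), rep(0, n))
  # propulsive (+x) AP force on a belt moving backwards at 1 m/s:
  # belt term = F_belt . v_belt = (-10) * (-1) = +10 W
  prop <- data.frame(fx = rep(10, n), fy = 0, fz = 0)
  expect_equal(leg_power(prop, v0, 1), rep(10, n))
  # braking force absorbs energy
  brake <- data.frame(fx = rep(-10, n), fy = 0, fz = 0)
  expect_equal(leg_power(brake, v0, 1), rep(-10, n))
  # full dot product with a moving COM
  v <- data.frame(vx = rep(0.2, n), vy = -0.1, vz = 0.3)
  f <- data.frame(fx = rep(5, n), fy = 4, fz = 600)
  expect_equal(leg_power(f, v, 1.5),
               rep(5 * 0.2 - 4 * 0.1 + 600 * 0.3 + 5 * 1.5, n))
  expect_error(leg_power(f[1:5, ], v, 1), "lengths")
})

test_that("stride work rates partition the signed power integral", {
  tt <- seq(0, 1, by = 0.01)
  w <- stride_work_rates(rep(70, length(tt)), tt, 1, 70)
  expect_equal(w$wpos, 1)
  expect_equal(w$wneg, 0)
  w2 <- stride_work_rates(sin(2 * pi * tt), tt, 1, 1)
  expect_equal(w2$wnet, 0, tolerance = 1e-12)
  expect_equal(w2$wpos, -w2$wneg, tolerance = 1e-12)
  # sign partition + conservation on an arbitrary smooth trace
  set.seed(8)
  p <- 50 * sin(2 * pi * tt * 2 + 1) + 20 * cos(2 * pi * tt * 5)
  w3 <- stride_work_rates(p, tt, 1, 70)
  expect_gte(w3$wpos, 0)
  expect_lte(w3$wneg, 0)
  expect_equal(w3$wpos + w3$wneg, trapz_oracle(tt, p) / 70,
               tolerance = 1e-9)
})

test_that("work rates agree with a 10x refined-grid quadrature", {
  tt <- seq(0, 1, by = 0.01)
  set.seed(12)
  p <- 80 * sin(2 * pi * tt * 1.5 + 0.3) + 30 * cos(2 * pi * tt * 4)
  w <- stride_work_rates(p, tt, 1, 70)
  tt10 <- seq(0, 1, by = 0.001)
  p10 <- approx(tt, p, tt10)$y
  wpos10 <- trapz_oracle(tt10, pmax(p10, 0)) / 70
  wneg10 <- trapz_oracle(tt10, pmin(p10, 0)) / 70
  expect_equal(w$wpos, wpos10, tolerance = 1e-3)
  expect_equal(w$wneg, wneg10, tolerance = 1e-3)
})

test_that("doubling mass at fixed forces halves mass-normalised rates", {
  tt <- seq(0, 1, by = 0.01)
  p <- 100 * sin(2 * pi * tt)
  w1 <- stride_work_rates(p, tt, 1, 70)
  w2 <- stride_work_rates(p, tt, 1, 140)
  expect_equal(w2$wpos, w1$wpos / 2)
  expect_equal(w2$wneg, w1$wneg / 2)
})

test_that("net work rate at end of adaptation averages the final strides", {
  expect_equal(net_work_rate_end(rep(0.2, 150)), 0.2)
  expect_equal(net_work_rate_end(c(rep(9, 50), rep(c(0.1, 0.3), 50))), 0.2)
  expect_error(net_work_rate_end(rep(0.2, 99)), "99")
})
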
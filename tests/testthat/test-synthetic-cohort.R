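test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(n_steps = 5), "n_steps")
  expect_error(synthetic_config(belt_speed_fast = 0.5, belt_speed_slow = 1),
               "exceed")
  cf <- adaptation_coefficients()
  cf$r_f[1] <- -1
  expect_error(synthetic_config(coeffs = cf), "positive")
})

test_that("noiseless generation reproduces the double-exponential curve", {
  cf <- adaptation_coefficients()
  cf$sigma_id <- 0
  cf$sigma_resid <- 0
  cfg <- synthetic_config(n_move = 1L, n_notmove = 1L, n_steps = 2000L,
                          coeffs = cf, seed = 3L)
  d <- generate_outcome_series(cfg, "sla")
  nm <- d[d$group == "notMOVE", ]
  # at large t the curve approaches the notMOVE plateau -0.043
  expect_equal(tail(nm$value, 1), -0.043, tolerance = 1e-3)
  expected <- -0.043 - 0.097 * exp(-nm$index / 32.465) -
    0.017 * exp(-nm$index / 162.122)
  expect_equal(nm$value, expected, tolerance = 1e-12)
})

test_that("all-zero coefficients with zero noise give an all-zero series", {
  cf <- adaptation_coefficients()
  cf[, c("c", "a_f", "a_s", "sigma_id", "sigma_resid")] <- 0
  cfg <- synthetic_config(coeffs = cf, n_steps = 20L)
  d <- generate_outcome_series(cfg, "sla")
  expect_true(all(d$value == 0))
})

test_that("residual noise matches the independently re-drawn sample SD", {
  cf <- adaptation_coefficients()
  cf[, c("c", "a_f", "a_s", "sigma_id")] <- 0
  cf$sigma_resid <- 0.032
  cfg <- synthetic_config(n_move = 1L, n_notmove = 1L, n_steps = 823L,
                          coeffs = cf, seed = 9L)
  d <- generate_outcome_series(cfg, "sla")
  expect_equal(sd(d$value), 0.032, tolerance = 0.032 * 0.1)
  # the same pseudo-random draws, reproduced independently of the generator
  set.seed(9L + 1000L * 1L)       # outcome sub-seed for "sla"
  b <- 0 * rnorm(2)
  set.seed(9L + 1000L * 1L + 1L)
  eps <- matrix(rnorm(823 * 2), nrow = 823) * 0.032
  expect_equal(d$value, c(eps[, 1], eps[, 2]))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- small_config()
  d1 <- generate_outcome_series(cfg, "wpos_slow")
  d2 <- generate_outcome_series(cfg, "wpos_slow")
  expect_identical(d1, d2)
})

test_that("work outcomes are stride-indexed at half the step count", {
  cfg <- small_config(n_steps = 61L)
  expect_equal(max(generate_outcome_series(cfg, "sla")$index), 61)
  expect_equal(max(generate_outcome_series(cfg, "wneg_fast")$index), 30)
  expect_error(generate_outcome_series(cfg, "bogus"))
})

test_that("plateau offsets have mean ~0 and SD ~sigma_id at large n", {
  cfg <- synthetic_config(n_move = 250L, n_notmove = 250L, seed = 21L)
  tr <- participant_truth(cfg, "sla")
  expect_lt(abs(mean(tr$b)), 0.006)
  expect_equal(sd(tr$b), 0.038, tolerance = 0.1)
})

test_that("the roster classifies into the configured group sizes", {
  cfg <- synthetic_config(seed = 2L)
  roster <- classify_roster(generate_participants(cfg, n_excluded = 5L))
  expect_equal(sum(roster$group == "MOVE"), 19)
  expect_equal(sum(roster$group == "notMOVE"), 13)
  expect_equal(sum(roster$group == "excluded"), 5)
  expect_equal(roster$group[roster$group_true != "excluded"],
               roster$group_true[roster$group_true != "excluded"])
})

test_that("raw trials round-trip through the processing chain", {
  fx <- fixture_trial(n = 30L)
  pr <- process_trial(fx$trial)
  st <- pr$steps
  expect_equal(nrow(st), 30)
  expect_lt(max(abs(st$step_length_fast_m - fx$sl_fast)), 0.01)
  expect_lt(max(abs(st$step_length_slow_m - fx$sl_slow)), 0.01)
  expect_lt(max(abs(st$sla - sla(fx$sl_fast, fx$sl_slow))), 0.01)
})

test_that("a symmetric trial yields near-zero SLA at every step", {
  cfg <- synthetic_config(seed = 1L)
  tr <- generate_raw_trial(rep(0.55, 20), rep(0.55, 20), cfg)
  st <- process_trial(tr)$steps
  expect_lt(max(abs(st$sla)), 0.01)
})

test_that("a constant 0.6/0.4 trial yields SLA ~0.2", {
  cfg <- synthetic_config(seed = 1L)
  tr <- generate_raw_trial(rep(0.6, 20), rep(0.4, 20), cfg)
  st <- process_trial(tr)$steps
  expect_equal(mean(st$sla), 0.2, tolerance = 0.02)
})

test_that("average vertical force equals body weight within 2%", {
  fx <- fixture_trial(n = 20L, mass_kg = 82)
  fz <- fx$trial$forces$fz_fast + fx$trial$forces$fz_slow
  expect_equal(mean(fz), 82 * 9.81, tolerance = 0.02)
})

test_that("invalid prescribed step lengths are rejected", {
  cfg <- synthetic_config(seed = 1L)
  expect_error(generate_raw_trial(c(0.6, -0.1), c(0.4, 0.4), cfg), "0, 1.5")
  expect_error(generate_raw_trial(rep(0.6, 3), rep(0.4, 2), cfg), "equal")
  expect_error(generate_raw_trial(rep(0.05, 5), rep(0.05, 5), cfg),
               "cadence")
})

test_that("raw trials write to and read from CSV/YAML unchanged", {
  fx <- fixture_trial(n = 8L)
  dir <- withr::local_tempdir()
  write_raw_trial(fx$trial, dir)
  tr2 <- read_raw_trial(dir)
  expect_equal(tr2$forces$fz_fast, fx$trial$forces$fz_fast,
               tolerance = 1e-6)
  expect_equal(tr2$mass_kg, fx$trial$mass_kg)
  expect_equal(tr2$events$time, fx$trial$events$time, tolerance = 1e-6)
})
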
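test_that("the adaptation curve has the right limits and hand value", {
  expect_equal(exp_predict(1e9, -0.04, -0.1, 30, -0.02, 160), -0.04)
  expect_equal(exp_predict(0, -0.04, -0.1, 30, -0.02, 160), -0.16)
  # two-exponent curve evaluated at t = r_f, by direct arithmetic
  v <- exp_predict(32.465, -0.043, -0.097, 32.465, -0.017, 162.122)
  expect_equal(v, -0.043 - 0.097 / exp(1) -
                 0.017 * exp(-32.465 / 162.122), tolerance = 1e-12)
  expect_error(exp_predict(1, 0, 1, -3), "positive")
  expect_error(exp_predict(1, 0, 1, 3, a_s = 1), "together")
})

test_that("marginal likelihood reduces to iid Gaussian when sigma_id = 0", {
  set.seed(31)
  inst <- random_small_instance()
  ll <- marginal_loglik(inst$data, inst$coef, 0, inst$sigma_resid)
  iid <- sum(vapply(unique(inst$data$id), function(pid) {
    d <- inst$data[inst$data$id == pid, ]
    row <- inst$coef[inst$coef$group == d$group[1], ]
    mu <- exp_predict(d$index, row$c, row$a_f, row$r_f, row$a_s, row$r_s)
    sum(dnorm(d$value, mu, inst$sigma_resid, log = TRUE))
  }, numeric(1)))
  expect_equal(ll, iid, tolerance = 1e-10)
})

test_that("marginal likelihood matches adaptive quadrature on small instances", {
  set.seed(100)
  for (i in 1:20) {
    inst <- random_small_instance()
    ll <- marginal_loglik(inst$data, inst$coef, inst$sigma_id,
                          inst$sigma_resid)
    expect_equal(ll, quad_loglik(inst$data, inst$coef, inst$sigma_id,
                                 inst$sigma_resid), tolerance = 1e-6)
  }
})

test_that("marginal likelihood is invariant to participant order", {
  set.seed(41)
  inst <- random_small_instance()
  ll1 <- marginal_loglik(inst$data, inst$coef, inst$sigma_id,
                         inst$sigma_resid)
  perm <- inst$data[rev(seq_len(nrow(inst$data))), ]
  expect_equal(marginal_loglik(perm, inst$coef, inst$sigma_id,
                               inst$sigma_resid), ll1)
})

test_that("near-noiseless data recover the generating curve", {
  cf <- adaptation_coefficients()[1:2, ]
  cf$sigma_id <- 0
  cf$sigma_resid <- 1e-5
  cfg <- synthetic_config(n_move = 3L, n_notmove = 3L, n_steps = 823L,
                          coeffs = cf, seed = 6L)
  d <- generate_outcome_series(cfg, "sla")
  f <- fit_ml(d, 2L, TRUE, se = FALSE)
  for (g in c("MOVE", "notMOVE")) {
    est <- f$coef[f$coef$group == g, ]
    tru <- cf[cf$group == g, ]
    for (nm in c("c", "a_f", "r_f", "a_s", "r_s"))
      expect_equal(est[[nm]], tru[[nm]], tolerance = 1e-3)
  }
})

test_that("model nesting: 2-exp likelihood never below 1-exp on same data", {
  cfg <- small_config(n_steps = 120L, seed = 14L)
  d <- generate_outcome_series(cfg, "sla")
  f1 <- fit_ml(d, 1L, FALSE, se = FALSE)
  f2 <- fit_ml(d, 1L, TRUE, se = FALSE)
  f3 <- fit_ml(d, 2L, FALSE, se = FALSE)
  f4 <- fit_ml(d, 2L, TRUE, se = FALSE)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
  expect_gte(f3$logLik, f1$logLik - 1e-6)
  expect_gte(f4$logLik, f2$logLik - 1e-6)
  expect_gte(f4$logLik, f3$logLik - 1e-6)
  # canonical slow/fast labelling
  expect_true(all(f4$coef$r_s > f4$coef$r_f))
  # information-criterion identities hold exactly for stored k and logLik
  for (f in list(f1, f2, f3, f4)) {
    expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
    expect_equal(f$BIC, f$k * log(f$n_obs) - 2 * f$logLik)
  }
})

test_that("fitted profiled optimum agrees with the exact marginal likelihood", {
  cfg <- small_config(n_steps = 100L, seed = 17L)
  d <- generate_outcome_series(cfg, "sla")
  f <- fit_ml(d, 2L, TRUE, se = FALSE)
  expect_equal(f$logLik,
               marginal_loglik(d, f$coef, f$sigma_id, f$sigma_resid),
               tolerance = 1e-6)
})

test_that("model comparison tabulates AIC/BIC and LRT correctly", {
  mkfit <- function(nm, ll, k, n_exp, grp) {
    structure(list(logLik = ll, k = k, AIC = 2 * k - 2 * ll,
                   BIC = k * log(1000) - 2 * ll, n_obs = 1000,
                   n_exponents = n_exp, group_effects = grp),
              class = "exp_model_fit")
  }
  fits <- list(exp1_pooled = mkfit("m1", 0, 2, 1, FALSE),
               exp2_group = mkfit("m4", 5, 7, 2, TRUE))
  cmp <- compare_models(fits)
  expect_equal(cmp$table$AIC[1], 4)        # AIC = 2k - 2l with l = 0, k = 2
  lrt <- cmp$lrt
  expect_equal(lrt$df, 5)
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$p, pchisq(10, 5, lower.tail = FALSE))
  bad <- fits; bad$exp2_group$n_obs <- 999
  expect_error(compare_models(bad), "identical")
})

test_that("group coefficient tests are near-null for identical groups", {
  cf <- adaptation_coefficients()[1:2, ]
  cf[cf$group == "MOVE", c("c", "a_f", "r_f", "a_s", "r_s")] <-
    cf[cf$group == "notMOVE", c("c", "a_f", "r_f", "a_s", "r_s")]
  cfg <- synthetic_config(n_move = 8L, n_notmove = 8L, n_steps = 300L,
                          coeffs = cf, seed = 19L)
  d <- generate_outcome_series(cfg, "sla")
  f <- fit_ml(d, 2L, TRUE, se = TRUE)
  gt <- coef_group_tests(f)
  expect_equal(nrow(gt), 5)
  # no coefficient should be wildly significant when groups share the truth
  expect_gt(min(gt$p), 1e-4)
  expect_true(all(is.finite(gt$se) & gt$se > 0))
})

test_that("truncation cuts all series to the shortest participant", {
  d <- rbind(data.frame(id = "A", group = "g", index = 1:830, value = 0),
             data.frame(id = "B", group = "g", index = 1:823, value = 0),
             data.frame(id = "C", group = "g", index = 1:900, value = 0))
  tr <- truncate_to_min(d)
  expect_equal(attr(tr, "n_common"), 823)
  expect_true(all(tapply(tr$index, tr$id, max) == 823))
  same <- truncate_to_min(d[d$id == "B", ])
  expect_equal(nrow(same), 823)
  expect_error(truncate_to_min(d[0, ]), "empty")
})

test_that("initial value averages the first strides", {
  expect_equal(initial_value(rep(-0.14, 10)), -0.14)
  expect_equal(initial_value(1:5), 3)
  expect_error(initial_value(1:3), "required")
})
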
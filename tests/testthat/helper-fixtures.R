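# Shared fixtures and independent oracles.

# Straightforward trapezoid rule, written independently of the package.
trapz_oracle <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# A small, fast cohort configuration for unit tests.
small_config <- function(n_steps = 60L, seed = 11L, ...) {
  synthetic_config(n_move = 4L, n_notmove = 3L, n_steps = n_steps,
                   seed = seed, ...)
}

# Independent marginal-likelihood oracle: numerically integrates the random
# plateau out of the joint density by adaptive quadrature, on the log scale
# to avoid underflow.
quad_loglik <- function(data, coef, sigma_id, sigma_resid) {
  ll <- 0
  for (pid in unique(data$id)) {
    d <- data[data$id == pid, ]
    row <- coef[coef$group == d$group[1L], ]
    mu <- if (!is.na(row$a_s))
      exp_predict(d$index, row$c, row$a_f, row$r_f, row$a_s, row$r_s)
    else exp_predict(d$index, row$c, row$a_f, row$r_f)
    logf <- function(b) vapply(b, function(bb) {
      sum(dnorm(d$value, mu + bb, sigma_resid, log = TRUE)) +
        dnorm(bb, 0, sigma_id, log = TRUE)
    }, numeric(1))
    # centre at the (conjugate) posterior mode of b
    n <- nrow(d)
    bhat <- sigma_id^2 * sum(d$value - mu) /
      (sigma_resid^2 + n * sigma_id^2)
    M <- logf(bhat)
    val <- integrate(function(b) exp(logf(b) - M),
                     bhat - 10 * sigma_id, bhat + 10 * sigma_id,
                     rel.tol = 1e-12)$value
    ll <- ll + M + log(val)
  }
  ll
}

# Random small data set + coefficient table for likelihood checks.
random_small_instance <- function() {
  groups <- c("A", "B")
  coef <- data.frame(group = groups, c = rnorm(2), a_f = rnorm(2),
                     r_f = runif(2, 2, 20), a_s = rnorm(2),
                     r_s = runif(2, 50, 300), stringsAsFactors = FALSE)
  n_id <- sample(2:4, 1)
  n_t <- sample(3:6, 1)
  data <- do.call(rbind, lapply(seq_len(n_id), function(i) {
    g <- sample(groups, 1)
    row <- coef[coef$group == g, ]
    mu <- exp_predict(seq_len(n_t), row$c, row$a_f, row$r_f, row$a_s,
                      row$r_s)
    data.frame(id = sprintf("P%d", i), group = g, index = seq_len(n_t),
               value = mu + rnorm(n_t, 0, 0.3), stringsAsFactors = FALSE)
  }))
  list(data = data, coef = coef,
       sigma_id = runif(1, 0.05, 0.5), sigma_resid = runif(1, 0.1, 0.5))
}

# A deterministic raw trial fixture (prescribed step lengths vary per step).
fixture_trial <- function(n = 30L, seed = 5L, fast_side = "left",
                          mass_kg = 70) {
  set.seed(seed)
  slf <- 0.62 + 0.02 * sin(seq_len(n) / 3)
  sls <- 0.48 + 0.015 * cos(seq_len(n) / 4)
  trial <- generate_raw_trial(slf, sls, synthetic_config(seed = seed),
                              mass_kg = mass_kg, fast_side = fast_side)
  list(trial = trial, sl_fast = slf, sl_slow = sls)
}
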
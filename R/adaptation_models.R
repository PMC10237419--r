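# One- and two-exponent adaptation curves with a participant-level random
# plateau, fitted by exact marginal maximum likelihood.
#
# Model, for participant i of group g at step/stride t:
#   y_it = c_g + b_i + a_f,g exp(-t / r_f,g) [+ a_s,g exp(-t / r_s,g)] + e_it
#   b_i ~ N(0, sigma_id^2),  e_it ~ N(0, sigma_resid^2)
# Because the random effect is additive, each participant's marginal
# distribution is multivariate normal with covariance
# sigma_resid^2 I + sigma_id^2 J, so the likelihood is available in closed
# form through the rank-one Woodbury and determinant identities -- no
# quadrature or linearisation is involved.

#' Evaluate an exponential adaptation curve
#'
#' `c + a_f exp(-t/r_f)` with an optional second component
#' `+ a_s exp(-t/r_s)`. At `t = 0` the curve equals `c + a_f (+ a_s)`; as
#' `t` grows it approaches the plateau `c`.
#'
#' @param t step or stride index (>= 0).
#' @param c plateau.
#' @param a_f,r_f fast component initial value and growth rate.
#' @param a_s,r_s optional slow component; both or neither.
#' @return Numeric vector of expected outcome values.
#' @export
exp_predict <- function(t, c, a_f, r_f, a_s = NULL, r_s = NULL) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (r_f <= 0) stop("growth rate r_f must be positive", call. = FALSE)
  y <- c + a_f * exp(-t / r_f)
  if (!is.null(a_s) || !is.null(r_s)) {
    if (is.null(a_s) || is.null(r_s))
      stop("a_s and r_s must be supplied together", call. = FALSE)
    if (r_s <= 0) stop("growth rate r_s must be positive", call. = FALSE)
    y <- y + a_s * exp(-t / r_s)
  }
  y
}

# Predicted curve for one group row of a coefficient table.
.predict_row <- function(t, row) {
  if (!is.na(row$a_s) && !is.na(row$r_s))
    exp_predict(t, row$c, row$a_f, row$r_f, row$a_s, row$r_s)
  else exp_predict(t, row$c, row$a_f, row$r_f)
}

#' Exact marginal log-likelihood of an adaptation model
#'
#' Sums, over participants, the multivariate-normal log-density of the
#' outcome series around the group curve, with covariance
#' `sigma_resid^2 I + sigma_id^2 J` (compound symmetry from the random
#' plateau), evaluated with the rank-one Woodbury/determinant identities.
#'
#' @param data long data.frame: `id`, `group`, `index`, `value`. For a
#'   pooled model set every group to the single row name in `coef`.
#' @param coef data.frame with one row per group: `group`, `c`, `a_f`,
#'   `r_f` and (for two-exponent models) `a_s`, `r_s` (NA otherwise).
#' @param sigma_id between-participant plateau SD (>= 0).
#' @param sigma_resid residual SD (> 0).
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(data, coef, sigma_id, sigma_resid) {
  if (sigma_resid <= 0) stop("sigma_resid must be positive", call. = FALSE)
  if (sigma_id < 0) stop("sigma_id must be non-negative", call. = FALSE)
  s2 <- sigma_resid^2; tau2 <- sigma_id^2
  ll <- 0
  for (pid in unique(data$id)) {
    d <- data[data$id == pid, ]
    g <- d$group[1L]
    row <- coef[coef$group == g, ]
    if (nrow(row) != 1L)
      stop(sprintf("no unique coefficient row for group '%s'", g),
           call. = FALSE)
    e <- d$value - .predict_row(d$index, row)
    n <- length(e)
    s <- sum(e)
    denom <- s2 + n * tau2
    logdet <- (n - 1) * log(s2) + log(denom)
    q <- (sum(e^2) - tau2 * s^2 / denom) / s2
    ll <- ll - 0.5 * (n * log(2 * pi) + logdet + q)
  }
  ll
}

# ---------------------------------------------------------------------------
# Profiled ML fitting
#
# For fixed growth rates and variance ratio lambda = sigma_id^2/sigma_resid^2
# the linear coefficients (c, a_f[, a_s] per group) solve a generalised
# least-squares system in closed form and sigma_resid^2 profiles out, so the
# numerical search runs over log-rates and log-lambda only. All
# participants share the index grid after truncation, so each group's
# design matrix is computed once per evaluation.

.prep_fit_data <- function(data, group_effects) {
  data <- data[order(data$id, data$index), ]
  ids <- unique(data$id)
  lens <- tapply(data$index, data$id, length)
  if (length(unique(lens)) != 1L)
    stop("participants have unequal series lengths; run truncate_to_min()",
         call. = FALSE)
  L <- unname(lens[1L])
  t <- data$index[data$id == ids[1L]]
  Y <- matrix(data$value, nrow = L)            # L x n, column per id
  colnames(Y) <- ids
  grp <- vapply(ids, function(i) data$group[data$id == i][1L], character(1))
  if (!group_effects) grp[] <- "pooled"
  groups <- sort(unique(grp))
  stats <- lapply(groups, function(g) {
    Yg <- Y[, grp == g, drop = FALSE]
    list(n = ncol(Yg), Y = Yg, Ysum = rowSums(Yg), s = colSums(Yg))
  })
  names(stats) <- groups
  list(t = t, L = L, n_id = length(ids), n_obs = L * length(ids),
       groups = groups, stats = stats, grp = grp, Y = Y, ids = ids)
}

.profiled_fit <- function(prep, rates_by_group, lambda, n_exp) {
  L <- prep$L; t <- prep$t
  w <- lambda / (1 + L * lambda)
  q_tot <- 0
  beta <- list()
  for (g in prep$groups) {
    r <- rates_by_group[[g]]
    X <- cbind(1, exp(-t / r[1L]))
    if (n_exp == 2L) X <- cbind(X, exp(-t / r[2L]))
    st <- prep$stats[[g]]
    XtX <- crossprod(X)
    cs <- colSums(X)
    A <- st$n * (XtX - w * tcrossprod(cs))
    b <- crossprod(X, st$Ysum) - w * cs * sum(st$s)
    bg <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(bg) || any(!is.finite(bg))) return(NULL)
    bg <- drop(bg)
    # residuals computed directly (quadratic-form shortcuts cancel
    # catastrophically when the design is near-singular)
    R <- st$Y - drop(X %*% bg)
    q_tot <- q_tot + sum(R^2) - w * sum(colSums(R)^2)
    beta[[g]] <- bg
  }
  if (q_tot <= 0) return(NULL)
  N <- prep$n_obs
  s2 <- q_tot / N
  ll <- -0.5 * (N * log(2 * pi * s2) + prep$n_id * log(1 + L * lambda) + N)
  list(ll = ll, beta = beta, sigma_resid = sqrt(s2),
       sigma_id = sqrt(lambda * s2))
}

#' Fit an adaptation mixed model by exact marginal maximum likelihood
#'
#' Fits `y = c + a_f exp(-t/r_f) [+ a_s exp(-t/r_s)]` with a participant-
#' level random plateau, by maximising the exact marginal Gaussian
#' likelihood. Growth rates and the variance ratio are searched on the log
#' scale from a grid of starting values (at least 5 starts); the linear
#' coefficients and residual variance are profiled out in closed form at
#' every evaluation. For two-exponent fits the components are canonicalised
#' so `r_s > r_f`; a fit where the two rates collapse is flagged degenerate.
#'
#' @param data long data.frame: `id`, `group`, `index`, `value`, with equal
#'   series lengths per participant (see [truncate_to_min()]).
#' @param n_exponents 1 or 2.
#' @param group_effects if `TRUE`, every curve coefficient differs by group.
#' @param se compute standard errors from the observed information (numeric
#'   Hessian of the exact marginal log-likelihood at the optimum).
#' @param extra_starts optional list of extra starting values, each
#'   `list(rates = <per-group vector>, lambda = <ratio>)`.
#' @return Object of class `exp_model_fit`: `coef` (per-group estimates and
#'   SEs), `sigma_id`, `sigma_resid`, `logLik`, `AIC`, `BIC`, `k`, `n_obs`,
#'   `n_participants`, `convergence`, `degenerate`, and (if `se`) the
#'   covariance of the estimates.
#' @export
fit_ml <- function(data, n_exponents = 2L, group_effects = TRUE,
                   se = TRUE, extra_starts = NULL) {
  n_exp <- as.integer(n_exponents)
  if (!n_exp %in% 1:2) stop("n_exponents must be 1 or 2", call. = FALSE)
  prep <- .prep_fit_data(data, group_effects)
  if (any(tapply(data$value, data$id, length) < 2))
    stop("every participant needs at least 2 observations", call. = FALSE)
  G <- length(prep$groups)

  unpack <- function(par) {
    nr <- n_exp * G
    rates <- exp(par[seq_len(nr)])
    rb <- split(rates, rep(prep$groups, each = n_exp))
    list(rates = rb, lambda = exp(par[nr + 1L]))
  }
  r_lo <- log(0.3); r_hi <- log(50 * prep$L)
  obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 25)) return(1e10)
    nr <- n_exp * G
    if (any(par[seq_len(nr)] < r_lo) || any(par[seq_len(nr)] > r_hi))
      return(1e10)
    u <- unpack(par)
    f <- .profiled_fit(prep, u$rates, u$lambda, n_exp)
    if (is.null(f) || !is.finite(f$ll)) return(1e10)
    -f$ll
  }

  starts <- list()
  if (n_exp == 2L) {
    for (rf in c(5, 20)) for (rs in c(100, 400))
      starts <- c(starts, list(list(rates = rep(c(rf, rs), G), lambda = 1)))
    starts <- c(starts, list(list(rates = rep(c(10, 200), G), lambda = 0.5)))
  } else {
    for (r in c(5, 20, 100, 400, 50))
      starts <- c(starts, list(list(rates = rep(r, G), lambda = 1)))
  }
  for (ex in extra_starts)
    starts <- c(starts, list(list(rates = rep(ex$rates, length.out = n_exp * G),
                                  lambda = ex$lambda)))

  best <- NULL
  conv <- 1L
  for (s in starts) {
    par0 <- c(log(s$rates), log(s$lambda))
    opt <- tryCatch(
      stats::optim(par0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence
    }
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)

  u <- unpack(best$par)
  f <- .profiled_fit(prep, u$rates, u$lambda, n_exp)
  coef <- do.call(rbind, lapply(prep$groups, function(g) {
    bg <- f$beta[[g]]
    r <- u$rates[[g]]
    if (n_exp == 2L)
      data.frame(group = g, c = bg[1L], a_f = bg[2L], r_f = r[1L],
                 a_s = bg[3L], r_s = r[2L], stringsAsFactors = FALSE)
    else
      data.frame(group = g, c = bg[1L], a_f = bg[2L], r_f = r[1L],
                 a_s = NA_real_, r_s = NA_real_, stringsAsFactors = FALSE)
  }))
  degenerate <- FALSE
  if (n_exp == 2L) {
    for (i in seq_len(nrow(coef))) {
      if (coef$r_f[i] > coef$r_s[i]) {       # canonical: slow rate larger
        coef[i, c("a_f", "r_f", "a_s", "r_s")] <-
          coef[i, c("a_s", "r_s", "a_f", "r_f")]
      }
      if (coef$r_s[i] / coef$r_f[i] < 1.05) degenerate <- TRUE
    }
  }

  # c and a's per group, rates per group, two variance components
  k <- (1L + n_exp) * G + n_exp * G + 2L
  ll <- f$ll
  fit <- structure(list(coef = coef, sigma_id = f$sigma_id,
                        sigma_resid = f$sigma_resid,
                        logLik = ll, k = k,
                        AIC = 2 * k - 2 * ll,
                        BIC = k * log(prep$n_obs) - 2 * ll,
                        n_obs = prep$n_obs, n_participants = prep$n_id,
                        n_exponents = n_exp, group_effects = group_effects,
                        convergence = conv, degenerate = degenerate),
                   class = "exp_model_fit")
  if (se) fit <- .add_standard_errors(fit, data)
  fit
}

# Observed-information standard errors on the full parameter vector
# (c, a_f, log r_f [, a_s, log r_s] per group, log sigma_id, log sigma_resid).
.add_standard_errors <- function(fit, data) {
  coef <- fit$coef
  n_exp <- fit$n_exponents
  groups <- coef$group
  if (!fit$group_effects) {
    data <- data
    data$group <- "pooled"
  }
  pack <- function() {
    th <- c()
    nm <- c()
    for (i in seq_along(groups)) {
      th <- c(th, coef$c[i], coef$a_f[i], log(coef$r_f[i]))
      nm <- c(nm, paste0(c("c", "a_f", "log_r_f"), ".", groups[i]))
      if (n_exp == 2L) {
        th <- c(th, coef$a_s[i], log(coef$r_s[i]))
        nm <- c(nm, paste0(c("a_s", "log_r_s"), ".", groups[i]))
      }
    }
    th <- c(th, log(max(fit$sigma_id, 1e-8)), log(fit$sigma_resid))
    nm <- c(nm, "log_sigma_id", "log_sigma_resid")
    names(th) <- nm
    th
  }
  nll <- function(th) {
    p <- 1L + 2L * n_exp
    cf <- do.call(rbind, lapply(seq_along(groups), function(i) {
      v <- th[((i - 1L) * p + 1L):(i * p)]
      if (n_exp == 2L)
        data.frame(group = groups[i], c = v[1L], a_f = v[2L],
                   r_f = exp(v[3L]), a_s = v[4L], r_s = exp(v[5L]),
                   stringsAsFactors = FALSE)
      else
        data.frame(group = groups[i], c = v[1L], a_f = v[2L],
                   r_f = exp(v[3L]), a_s = NA_real_, r_s = NA_real_,
                   stringsAsFactors = FALSE)
    }))
    np <- length(th)
    -marginal_loglik(data, cf, exp(th[np - 1L]), exp(th[np]))
  }
  th <- pack()
  H <- tryCatch(stats::optimHess(th, nll), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V)) {
    fit$vcov <- NULL
    return(fit)
  }
  dimnames(V) <- list(names(th), names(th))
  fit$vcov <- V
  se_of <- function(nm) sqrt(pmax(diag(V)[nm], 0))
  for (i in seq_along(groups)) {
    g <- groups[i]
    fit$coef$c_se[i] <- se_of(paste0("c.", g))
    fit$coef$a_f_se[i] <- se_of(paste0("a_f.", g))
    fit$coef$r_f_se[i] <- fit$coef$r_f[i] * se_of(paste0("log_r_f.", g))
    if (n_exp == 2L) {
      fit$coef$a_s_se[i] <- se_of(paste0("a_s.", g))
      fit$coef$r_s_se[i] <- fit$coef$r_s[i] * se_of(paste0("log_r_s.", g))
    }
  }
  fit
}

#' @export
print.exp_model_fit <- function(x, ...) {
  cat(sprintf("%d-exponent adaptation model (%s), random plateau\n",
              x$n_exponents,
              if (x$group_effects) "group fixed effects" else "pooled"))
  print(x$coef, row.names = FALSE, digits = 4)
  cat(sprintf("sigma_id = %.4f, sigma_resid = %.4f\n", x$sigma_id,
              x$sigma_resid))
  cat(sprintf("logLik = %.2f, k = %d, AIC = %.2f, BIC = %.2f, n = %d obs / %d participants\n",
              x$logLik, x$k, x$AIC, x$BIC, x$n_obs, x$n_participants))
  if (x$degenerate) cat("NOTE: degenerate fit (r_s ~ r_f)\n")
  invisible(x)
}

#' Compare the candidate model ladder
#'
#' Given fits of the four candidate models (one/two exponents, with/without
#' group effects) on identical data, tabulates k, log-likelihood, AIC and
#' BIC, runs likelihood-ratio chi-squared tests for the nested pairs, and
#' selects the model with the lowest AIC (flagging any disagreement with
#' BIC).
#'
#' @param fits named list of `exp_model_fit` objects.
#' @return list: `table` (one row per model), `lrt` (nested-pair tests),
#'   `chosen_aic`, `chosen_bic`, `agree`.
#' @export
compare_models <- function(fits) {
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1L)
    stop("fits were not computed on identical data (n_obs differs)",
         call. = FALSE)
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, n_exponents = f$n_exponents,
               group_effects = f$group_effects, k = f$k,
               logLik = f$logLik, AIC = f$AIC, BIC = f$BIC,
               stringsAsFactors = FALSE)
  }))
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  nested <- function(a, b) {           # is a nested in b?
    a$n_exponents <= b$n_exponents &&
      (!a$group_effects || b$group_effects) && a$k < b$k
  }
  lrt <- NULL
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j || !nested(fits[[i]], fits[[j]])) next
    df <- fits[[j]]$k - fits[[i]]$k
    stat <- 2 * (fits[[j]]$logLik - fits[[i]]$logLik)
    lrt <- rbind(lrt, data.frame(
      null = names(fits)[i], alt = names(fits)[j], df = df,
      statistic = stat,
      p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  chosen_aic <- tab$model[which.min(tab$AIC)]
  chosen_bic <- tab$model[which.min(tab$BIC)]
  list(table = tab, lrt = lrt, chosen_aic = chosen_aic,
       chosen_bic = chosen_bic, agree = identical(chosen_aic, chosen_bic))
}

#' Wald tests of group differences in curve coefficients
#'
#' For each fitted coefficient, the MOVE - notMOVE difference, its standard
#' error from the joint covariance of the estimates (delta method for the
#' log-parameterised growth rates), a t statistic and a two-sided p-value.
#'
#' @param fit a converged `exp_model_fit` with group effects and `vcov`.
#' @param groups character(2): the two group labels, difference is
#'   `groups[1] - groups[2]`.
#' @return data.frame: coefficient, estimate per group, difference, se, t,
#'   df, p.
#' @export
coef_group_tests <- function(fit, groups = c("MOVE", "notMOVE")) {
  if (!fit$group_effects)
    stop("fit has no group effects to test", call. = FALSE)
  if (is.null(fit$vcov))
    stop("fit carries no covariance (refit with se = TRUE)", call. = FALSE)
  V <- fit$vcov
  cf <- fit$coef
  i1 <- match(groups[1L], cf$group); i2 <- match(groups[2L], cf$group)
  if (anyNA(c(i1, i2))) stop("groups not found in fit", call. = FALSE)
  terms <- c("c", "a_f", "r_f")
  if (fit$n_exponents == 2L) terms <- c(terms, "a_s", "r_s")
  df <- fit$n_obs - fit$k
  out <- do.call(rbind, lapply(terms, function(tm) {
    est1 <- cf[[tm]][i1]; est2 <- cf[[tm]][i2]
    if (tm %in% c("r_f", "r_s")) {
      n1 <- paste0("log_", tm, ".", groups[1L])
      n2 <- paste0("log_", tm, ".", groups[2L])
      var_d <- est1^2 * V[n1, n1] + est2^2 * V[n2, n2] -
        2 * est1 * est2 * V[n1, n2]
    } else {
      n1 <- paste0(tm, ".", groups[1L]); n2 <- paste0(tm, ".", groups[2L])
      var_d <- V[n1, n1] + V[n2, n2] - 2 * V[n1, n2]
    }
    if (!is.finite(var_d) || var_d <= 0)
      stop("singular covariance for coefficient ", tm, call. = FALSE)
    d <- est1 - est2
    tt <- d / sqrt(var_d)
    data.frame(coefficient = tm, estimate_1 = est1, estimate_2 = est2,
               difference = d, se = sqrt(var_d), t = tt, df = df,
               p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- paste0("estimate_", groups)
  out
}

#' Truncate all participants to the shortest series
#'
#' Every participant's series is cut to the minimum number of observations
#' present in the set, so each participant weights equally on each index.
#'
#' @param data long data.frame with `id` and `index` columns.
#' @return The truncated data.frame, with the common length in attribute
#'   `"n_common"`.
#' @export
truncate_to_min <- function(data) {
  if (nrow(data) == 0L) stop("empty series set", call. = FALSE)
  lens <- tapply(data$index, data$id, length)
  L <- min(lens)
  out <- do.call(rbind, lapply(split(data, data$id), function(d) {
    d[order(d$index), ][seq_len(L), ]
  }))
  rownames(out) <- NULL
  attr(out, "n_common") <- L
  out
}

#' Initial value of an adaptation series
#'
#' Mean over the first `n_first` observations (default 5 strides).
#'
#' @param x numeric series in index order.
#' @param n_first how many initial observations to average.
#' @return Scalar mean.
#' @export
initial_value <- function(x, n_first = 5L) {
  if (length(x) < n_first)
    stop(sprintf("series has %d values; %d required", length(x), n_first),
         call. = FALSE)
  mean(x[seq_len(n_first)])
}
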
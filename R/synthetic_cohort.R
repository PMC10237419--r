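# Synthetic two-group split-belt adaptation cohort.
#
# The generator stands in for an undeposited experimental data set. Stride- or
# step-indexed outcome series follow a double-exponential adaptation curve
#   y_it = c_g + b_i + a_f * exp(-t / r_f) + a_s * exp(-t / r_s) + eps_it
# with a participant-level plateau offset b_i ~ N(0, sigma_id^2) and residual
# noise eps_it ~ N(0, sigma_resid^2). Raw marker/force signals can be
# synthesised for any prescribed per-step step-length sequence so the whole
# processing chain (filtering, event detection, step lengths, per-leg work)
# can be exercised against known ground truth.

.outcome_ids <- c("sla", "wpos_fast", "wpos_slow", "wneg_fast", "wneg_slow")

#' Published two-timescale adaptation coefficients
#'
#' Generating fixed effects (plateau `c`, fast/slow component initial values
#' `a_f`, `a_s`, growth rates `r_f`, `r_s`) for each outcome and group, plus
#' between-participant plateau SD (`sigma_id`) and residual SD
#' (`sigma_resid`). These are the full-precision values reported for a
#' 19 MOVE / 13 notMOVE young-adult cohort walking 10 minutes on a 2:1
#' split-belt treadmill; they are the ground truth the default synthetic
#' cohort is generated from.
#'
#' @return A data.frame with one row per (outcome, group).
#' @export
adaptation_coefficients <- function() {
  out <- rbind(
    data.frame(outcome = "sla", group = c("notMOVE", "MOVE"),
               c = c(-0.043, -0.033), a_f = c(-0.097, -0.078),
               r_f = c(32.465, 11.628), a_s = c(-0.017, -0.060),
               r_s = c(162.122, 396.341),
               sigma_id = 0.038, sigma_resid = 0.032),
    data.frame(outcome = "wpos_fast", group = c("notMOVE", "MOVE"),
               c = c(0.54, 0.68), a_f = c(0.38, 0.56),
               r_f = c(5.19, 6.78), a_s = c(0.66, 0.36),
               r_s = c(86.45, 157.47),
               sigma_id = 0.435, sigma_resid = 0.259),
    data.frame(outcome = "wpos_slow", group = c("notMOVE", "MOVE"),
               c = c(0.20, 0.36), a_f = c(0.28, 0.55),
               r_f = c(7.56, 3.45), a_s = c(0.32, 0.05),
               r_s = c(629.28, 321.16),
               sigma_id = 0.231, sigma_resid = 0.147),
    data.frame(outcome = "wneg_fast", group = c("notMOVE", "MOVE"),
               c = c(-0.28, -0.24), a_f = c(0.02, -0.15),
               r_f = c(31.94, 1.86), a_s = c(0.03, 0.12),
               r_s = c(1.12, 433.6),
               sigma_id = 0.347, sigma_resid = 0.150),
    data.frame(outcome = "wneg_slow", group = c("notMOVE", "MOVE"),
               c = c(-0.48, -0.68), a_f = c(-0.60, -0.831),
               r_f = c(6.26, 6.76), a_s = c(-0.66, -0.40),
               r_s = c(101.41, 156.07),
               sigma_id = 0.572, sigma_resid = 0.288)
  )
  rownames(out) <- NULL
  out
}

#' Build a synthetic cohort configuration
#'
#' @param n_move,n_notmove group sizes (defaults: 19 MOVE, 13 notMOVE).
#' @param n_steps steps per participant (default 823, the common truncation
#'   length); work outcomes are stride-indexed with `floor(n_steps / 2)`
#'   strides.
#' @param coeffs data.frame in the format of [adaptation_coefficients()];
#'   generating fixed effects and variance components per outcome and group.
#' @param belt_speed_fast,belt_speed_slow belt speeds in m/s (2:1 ratio by
#'   default).
#' @param mass_mean,mass_sd body mass distribution, kg.
#' @param seed integer master seed; every stochastic draw is derived from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_move = 19L, n_notmove = 13L, n_steps = 823L,
                             coeffs = adaptation_coefficients(),
                             belt_speed_fast = 1.5, belt_speed_slow = 0.75,
                             mass_mean = 70.3, mass_sd = 13,
                             seed = 1L) {
  stopifnot_scalar(n_move, "n_move", positive = TRUE)
  stopifnot_scalar(n_notmove, "n_notmove", positive = TRUE)
  stopifnot_scalar(n_steps, "n_steps")
  if (n_steps < 10) stop("n_steps must be >= 10", call. = FALSE)
  need <- c("outcome", "group", "c", "a_f", "r_f", "a_s", "r_s",
            "sigma_id", "sigma_resid")
  if (!all(need %in% names(coeffs)))
    stop("coeffs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(coeffs$r_f <= 0) || any(coeffs$r_s <= 0))
    stop("growth rates r_f, r_s must be positive", call. = FALSE)
  if (any(coeffs$sigma_id < 0) || any(coeffs$sigma_resid < 0))
    stop("variance components must be non-negative", call. = FALSE)
  stopifnot_scalar(belt_speed_fast, "belt_speed_fast", positive = TRUE)
  stopifnot_scalar(belt_speed_slow, "belt_speed_slow", positive = TRUE)
  if (belt_speed_fast <= belt_speed_slow)
    stop("belt_speed_fast must exceed belt_speed_slow", call. = FALSE)
  stopifnot_scalar(mass_mean, "mass_mean", positive = TRUE)
  stopifnot_scalar(mass_sd, "mass_sd")
  structure(list(n_move = as.integer(n_move),
                 n_notmove = as.integer(n_notmove),
                 n_steps = as.integer(n_steps),
                 coeffs = coeffs,
                 belt_speed_fast = belt_speed_fast,
                 belt_speed_slow = belt_speed_slow,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic split-belt cohort configuration\n")
  cat(sprintf("  groups: %d MOVE, %d notMOVE; %d steps per participant\n",
              x$n_move, x$n_notmove, x$n_steps))
  cat(sprintf("  belts: %.2f / %.2f m/s; mass %.1f (SD %.1f) kg; seed %d\n",
              x$belt_speed_fast, x$belt_speed_slow, x$mass_mean, x$mass_sd,
              x$seed))
  invisible(x)
}

# Per-outcome sub-seed: counter scheme so each outcome's draws are
# independent of the others and of roster draws.
.outcome_seed <- function(config, outcome) {
  config$seed + 1000L * match(outcome, .outcome_ids)
}

#' Participant-level ground truth for one outcome
#'
#' Draws the roster (group labels, masses, fast-leg side) and the
#' participant-level plateau offsets b_i ~ N(0, sigma_id^2) for the given
#' outcome, under the configuration's seed.
#'
#' @param config a [synthetic_config()].
#' @param outcome one of `"sla"`, `"wpos_fast"`, `"wpos_slow"`,
#'   `"wneg_fast"`, `"wneg_slow"`.
#' @return data.frame: id, group, b (plateau offset), mass_kg, fast_side.
#' @export
participant_truth <- function(config, outcome = "sla") {
  outcome <- match.arg(outcome, .outcome_ids)
  n <- config$n_move + config$n_notmove
  cf <- config$coeffs[config$coeffs$outcome == outcome, ]
  set.seed(.outcome_seed(config, outcome))
  b <- cf$sigma_id[1L] * rnorm(n)
  set.seed(config$seed)                      # roster draws shared by outcomes
  mass <- pmax(40, config$mass_mean + config$mass_sd * rnorm(n))
  fast_side <- sample(c("right", "left"), n, replace = TRUE,
                      prob = c(6, 26) / 32)
  data.frame(id = sprintf("P%02d", seq_len(n)),
             group = rep(c("MOVE", "notMOVE"),
                         c(config$n_move, config$n_notmove)),
             b = b, mass_kg = mass, fast_side = fast_side,
             stringsAsFactors = FALSE)
}

#' Generate a stride- or step-indexed outcome series for the whole cohort
#'
#' Step length asymmetry is step-indexed with `n_steps` observations per
#' participant; work-rate outcomes are stride-indexed with
#' `floor(n_steps / 2)` observations.
#'
#' @inheritParams participant_truth
#' @return Long data.frame: id, group, index (1-based), value. The
#'   participant truth table is attached as attribute `"truth"`.
#' @export
generate_outcome_series <- function(config, outcome = "sla") {
  outcome <- match.arg(outcome, .outcome_ids)
  truth <- participant_truth(config, outcome)
  cf <- config$coeffs[config$coeffs$outcome == outcome, ]
  len <- if (outcome == "sla") config$n_steps else config$n_steps %/% 2L
  t <- seq_len(len)
  n <- nrow(truth)
  set.seed(.outcome_seed(config, outcome) + 1L)
  eps <- matrix(rnorm(len * n), nrow = len) * cf$sigma_resid[1L]
  curves <- lapply(c(MOVE = "MOVE", notMOVE = "notMOVE"), function(g) {
    p <- cf[cf$group == g, ]
    exp_predict(t, c = p$c, a_f = p$a_f, r_f = p$r_f,
                a_s = p$a_s, r_s = p$r_s)
  })
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- truth$group[i]
    data.frame(id = truth$id[i], group = g, index = t,
               value = curves[[g]] + truth$b[i] + eps[, i],
               stringsAsFactors = FALSE)
  }))
  attr(out, "truth") <- truth
  attr(out, "outcome") <- outcome
  out
}

#' Generate a synthetic questionnaire/demographics roster
#'
#' Emulates the study's screening: `n_excluded` extra participants whose only
#' modalities are strength/flexibility types (they classify as excluded),
#' MOVE participants reporting >= 150 min/week of moderate-to-vigorous
#' exercise for >= 13 consecutive weeks, notMOVE below 150 min/week. Sex and
#' fast-leg counts follow the study's marginals (11F/2M and 3R/10L in
#' notMOVE; 11F/8M and 3R/16L in MOVE, scaled to the configured group sizes).
#'
#' @inheritParams participant_truth
#' @param n_excluded how many excluded-modality participants to append.
#' @return data.frame of participant records (one row each).
#' @export
generate_participants <- function(config, n_excluded = 5L) {
  truth <- participant_truth(config, "sla")
  n <- nrow(truth)
  set.seed(config$seed + 77L)
  is_move <- truth$group == "MOVE"
  minutes <- ifelse(is_move, round(runif(n, 150, 750)), round(runif(n, 0, 120)))
  weeks <- round(runif(n, 13, 104))
  aerobic <- c("run", "cycle", "basketball", "tennis", "dance", "boxing")
  modal <- vapply(seq_len(n), function(i) {
    if (minutes[i] == 0) return("")
    paste(sample(aerobic, sample(1:2, 1)), collapse = ";")
  }, character(1))
  sex <- unlist(lapply(c("MOVE", "notMOVE"), function(g) {
    ng <- sum(truth$group == g)
    nm <- round(ng * if (g == "MOVE") 8 / 19 else 2 / 13)
    sample(rep(c("M", "F"), c(nm, ng - nm)))
  }))
  age <- ifelse(is_move, round(runif(n, 19, 32)), round(runif(n, 19, 22)))
  height <- round(runif(n, 154, 192), 1)
  rec <- data.frame(id = truth$id, group_true = truth$group, age_yr = age,
                    height_cm = height, mass_kg = round(truth$mass_kg, 1),
                    sex = sex, minutes_per_week = minutes,
                    consecutive_weeks = weeks, modalities = modal,
                    fast_side = truth$fast_side, stringsAsFactors = FALSE)
  if (n_excluded > 0) {
    strength <- c("weightlifting", "yoga", "scuba diving")
    exc <- data.frame(id = sprintf("X%02d", seq_len(n_excluded)),
                      group_true = "excluded",
                      age_yr = round(runif(n_excluded, 19, 35)),
                      height_cm = round(runif(n_excluded, 154, 192), 1),
                      mass_kg = round(config$mass_mean +
                                        config$mass_sd * rnorm(n_excluded), 1),
                      sex = sample(c("M", "F"), n_excluded, replace = TRUE),
                      minutes_per_week = round(runif(n_excluded, 60, 400)),
                      consecutive_weeks = round(runif(n_excluded, 13, 104)),
                      modalities = replicate(n_excluded,
                        paste(sample(strength, sample(1:2, 1)),
                              collapse = ";")),
                      fast_side = sample(c("right", "left"), n_excluded,
                                         replace = TRUE),
                      stringsAsFactors = FALSE)
    rec <- rbind(rec, exc)
  }
  rec
}

# ---------------------------------------------------------------------------
# Raw-signal synthesis

#' Synthesise a raw marker/force trial for prescribed step lengths
#'
#' Builds ankle-marker trajectories and per-belt ground reaction forces that,
#' when run through the standard processing chain (low-pass filtering,
#' threshold foot-strike detection, ankle separation at strike), reproduce
#' the prescribed per-step step lengths. Stance vertical force is a half-sine
#' scaled so the trial-average vertical force on the two belts sums to body
#' weight; the anterior-posterior force is a braking-then-propulsion sinusoid
#' with zero net impulse per stance. Timing: stride period for step pair k is
#' `(sl_fast[k] + sl_slow[k]) / mean(belt speeds)`, symmetric step timing,
#' duty factor 0.6.
#'
#' @param sl_fast,sl_slow prescribed step lengths (m) at fast-leg and
#'   slow-leg strikes; equal length, strikes alternate starting with fast.
#' @param config a [synthetic_config()] (belt speeds).
#' @param mass_kg body mass.
#' @param fast_side `"left"` or `"right"`.
#' @param id participant identifier.
#' @param ap_force_frac peak AP force as a fraction of the vertical peak.
#' @return Object of class `raw_trial`: `forces` (1000 Hz data.frame),
#'   `markers` (100 Hz data.frame), metadata, and the true event schedule in
#'   `$events` for oracle checks.
#' @export
generate_raw_trial <- function(sl_fast, sl_slow, config,
                               mass_kg = 70, fast_side = "left",
                               id = "P01", ap_force_frac = 0.15) {
  if (length(sl_fast) != length(sl_slow))
    stop("sl_fast and sl_slow must have equal length", call. = FALSE)
  if (any(sl_fast <= 0) || any(sl_slow <= 0) ||
      any(sl_fast >= 1.5) || any(sl_slow >= 1.5))
    stop("prescribed step lengths must lie in (0, 1.5) m", call. = FALSE)
  v_f <- config$belt_speed_fast
  v_s <- config$belt_speed_slow
  v_mean <- (v_f + v_s) / 2
  n_pair <- length(sl_fast)
  T_stride <- (sl_fast + sl_slow) / v_mean      # per step pair
  if (any(T_stride < 0.4))
    stop("prescribed step lengths imply cadence above 150 strides/min; ",
         "incompatible with belt speeds", call. = FALSE)
  duty <- 0.6

  # Event schedule: fast strike k, then slow strike half a stride later.
  t_fast <- 0.5 + T_stride[1L] / 2 + c(0, cumsum(T_stride[-n_pair]))
  t_slow <- t_fast + T_stride / 2

  # Strike positions of the ankle markers (anterior-posterior axis).
  # Leading ankle = trailing (contralateral, mid-stance) ankle + step length.
  x_fast <- numeric(n_pair); x_slow <- numeric(n_pair)
  x_fast[1L] <- 0.3
  for (k in seq_len(n_pair)) {
    x_slow[k] <- (x_fast[k] - v_f * (T_stride[k] / 2)) + sl_slow[k]
    if (k < n_pair)
      x_fast[k + 1L] <- (x_slow[k] - v_s * (T_stride[k] / 2)) + sl_fast[k + 1L]
  }

  # Kinematic-only slow stance before the first fast strike so the first
  # fast step length is well defined; it carries no force, so it produces
  # no gait event.
  t_slow0 <- t_fast[1L] - T_stride[1L] / 2
  x_slow0 <- x_fast[1L] - sl_fast[1L] + v_s * T_stride[1L] / 2

  t_end <- t_fast[n_pair] + T_stride[n_pair] + 0.5

  ankle_x <- function(strikes, xs, v_belt, stance_dur, t) {
    # Stance: constant -v_belt from each strike.  Swing: quintic Hermite with
    # end velocities matched to the belt, so the full trajectory is C2 and
    # survives 6 Hz low-pass filtering without displacing the strike position.
    x <- numeric(length(t))
    n <- length(strikes)
    for (k in seq_len(n)) {
      s0 <- strikes[k]; s1 <- s0 + stance_dur[k]
      in_st <- t >= s0 & t < s1
      x[in_st] <- xs[k] - v_belt * (t[in_st] - s0)
      if (k < n) {
        sw0 <- s1; sw1 <- strikes[k + 1L]
        tau <- sw1 - sw0
        in_sw <- t >= sw0 & t < sw1
        u <- (t[in_sw] - sw0) / tau
        s <- u^3 * (10 - 15 * u + 6 * u^2)     # smoothstep, s'=s''=0 at ends
        x0 <- xs[k] - v_belt * stance_dur[k]
        x[in_sw] <- x0 - v_belt * tau * u +
          (xs[k + 1L] - x0 + v_belt * tau) * s
      }
    }
    x[t < strikes[1L]] <- xs[1L] - v_belt * (t[t < strikes[1L]] - strikes[1L])
    last_end <- strikes[n] + stance_dur[n]
    x[t >= last_end] <- xs[n] - v_belt * stance_dur[n]
    x
  }
  swing_z <- function(strikes, stance_dur, t, z0 = 0.10, lift = 0.08) {
    z <- rep(z0, length(t))
    n <- length(strikes)
    for (k in seq_len(n - 1L)) {
      sw0 <- strikes[k] + stance_dur[k]; sw1 <- strikes[k + 1L]
      in_sw <- t >= sw0 & t < sw1
      u <- (t[in_sw] - sw0) / (sw1 - sw0)
      z[in_sw] <- z0 + lift * sin(pi * u)^2    # C1 at stance boundaries
    }
    z
  }

  fs_m <- 100; fs_f <- 1000
  t_m <- seq(0, t_end, by = 1 / fs_m)
  t_f <- seq(0, t_end, by = 1 / fs_f)
  stance_f <- duty * T_stride
  stance_s <- duty * T_stride

  xf <- ankle_x(t_fast, x_fast, v_f, stance_f, t_m)
  xs_ <- ankle_x(c(t_slow0, t_slow), c(x_slow0, x_slow), v_s,
                 c(duty * T_stride[1L], stance_s), t_m)
  zf <- swing_z(t_fast, stance_f, t_m)
  zs <- swing_z(c(t_slow0, t_slow), c(duty * T_stride[1L], stance_s), t_m)
  y_fast <- if (fast_side == "left") 0.10 else -0.10

  mk <- data.frame(time_s = t_m)
  add_marker <- function(mk, name, x, y, z) {
    mk[[paste0(name, "_x")]] <- x
    mk[[paste0(name, "_y")]] <- y
    mk[[paste0(name, "_z")]] <- z
    mk
  }
  pelvis_x <- 0.02 * sin(2 * pi * t_m / mean(T_stride))
  mk <- add_marker(mk, "ASIS_L", pelvis_x, 0.12, 0.95)
  mk <- add_marker(mk, "ASIS_R", pelvis_x, -0.12, 0.95)
  if (fast_side == "left") {
    mk <- add_marker(mk, "ANK_L", xf, y_fast, zf)
    mk <- add_marker(mk, "ANK_R", xs_, -y_fast, zs)
  } else {
    mk <- add_marker(mk, "ANK_R", xf, y_fast, zf)
    mk <- add_marker(mk, "ANK_L", xs_, -y_fast, zs)
  }

  # Vertical force amplitude: trial-average vertical force (both belts)
  # equals body weight.  Mean of a half-sine over its stance is (2/pi) * A.
  g <- 9.81
  total_stance <- sum(stance_f) + sum(stance_s)
  A <- mass_kg * g * t_end / ((2 / pi) * total_stance)

  belt_force <- function(strikes, stance_dur, t) {
    fz <- numeric(length(t)); fx <- numeric(length(t))
    for (k in seq_along(strikes)) {
      s0 <- strikes[k]; s1 <- s0 + stance_dur[k]
      in_st <- t >= s0 & t < s1
      u <- (t[in_st] - s0) / (s1 - s0)
      fz[in_st] <- A * sin(pi * u)
      fx[in_st] <- -ap_force_frac * A * sin(2 * pi * u)
    }
    list(fx = fx, fz = fz)
  }
  ff <- belt_force(t_fast, stance_f, t_f)
  fsl <- belt_force(t_slow, stance_s, t_f)
  forces <- data.frame(time_s = t_f,
                       fx_fast = ff$fx, fy_fast = 0, fz_fast = ff$fz,
                       fx_slow = fsl$fx, fy_slow = 0, fz_slow = fsl$fz)

  structure(list(forces = forces, markers = mk, mass_kg = mass_kg,
                 belt_speed_fast = v_f, belt_speed_slow = v_s,
                 fast_side = fast_side, id = id,
                 events = data.frame(
                   time = c(t_fast, t_slow),
                   leg = rep(c("fast", "slow"), each = n_pair))[
                     order(c(t_fast, t_slow)), ],
                 prescribed = data.frame(step = seq_len(n_pair),
                                         sl_fast = sl_fast,
                                         sl_slow = sl_slow)),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("Raw split-belt trial %s: %d step pairs, %.1f s, %.0f kg, fast leg %s\n",
              x$id, nrow(x$prescribed), max(x$forces$time_s), x$mass_kg,
              x$fast_side))
  invisible(x)
}

#' Write / read a raw trial as plain CSV + YAML metadata
#'
#' `forces.csv` holds the 1000 Hz per-belt ground reaction forces (N),
#' `markers.csv` the 100 Hz marker trajectories (m), `meta.yaml` mass, belt
#' speeds, fast side and the true event schedule.
#'
#' @param trial a `raw_trial`.
#' @param dir output directory (created if needed).
#' @return `write_raw_trial`: the directory, invisibly. `read_raw_trial`: a
#'   `raw_trial` (without the prescribed step-length table).
#' @export
write_raw_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$forces, file.path(dir, "forces.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(id = trial$id, mass_kg = trial$mass_kg,
                        belt_speed_fast = trial$belt_speed_fast,
                        belt_speed_slow = trial$belt_speed_slow,
                        fast_side = trial$fast_side,
                        event_time = trial$events$time,
                        event_leg = trial$events$leg),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_raw_trial
#' @export
read_raw_trial <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(forces = utils::read.csv(file.path(dir, "forces.csv")),
                 markers = utils::read.csv(file.path(dir, "markers.csv")),
                 mass_kg = meta$mass_kg,
                 belt_speed_fast = meta$belt_speed_fast,
                 belt_speed_slow = meta$belt_speed_slow,
                 fast_side = meta$fast_side, id = meta$id,
                 events = data.frame(time = meta$event_time,
                                     leg = meta$event_leg),
                 prescribed = NULL),
            class = "raw_trial")
}
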
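# Step lengths, step length asymmetry, and per-leg mechanical work from
# ground reaction forces via the individual-limbs (point-mass) method.

#' Step length asymmetry
#'
#' `sla = (fast - slow) / (fast + slow)`: 0 for symmetric steps, negative
#' when the leg on the slow belt takes the longer step. Vectorized.
#'
#' @param step_length_fast,step_length_slow step lengths, m.
#' @return Dimensionless asymmetry in (-1, 1).
#' @export
sla <- function(step_length_fast, step_length_slow) {
  s <- step_length_fast + step_length_slow
  if (any(s <= 0))
    stop("step lengths must have a positive sum", call. = FALSE)
  (step_length_fast - step_length_slow) / s
}

#' Step lengths at foot strike from ankle markers
#'
#' At each detected foot strike, the step length is the anterior-posterior
#' distance between the two ankle markers, assigned to the striking leg's
#' belt. Marker positions are linearly interpolated to the event time
#' (sub-sample timing error at 100 Hz is far below step-length noise).
#' Consecutive fast/slow steps are then paired into a step index and SLA
#' computed per pair.
#'
#' @param markers marker data.frame (filtered), with `time_s` and
#'   `ANK_L_x` / `ANK_R_x` columns.
#' @param events a `gait_events` table.
#' @param fast_side `"left"` or `"right"`: which ankle is on the fast belt.
#' @return data.frame of class `step_series`: step, step_length_fast_m,
#'   step_length_slow_m, sla.
#' @export
step_length_at_strike <- function(markers, events, fast_side = "left") {
  tmin <- min(markers$time_s); tmax <- max(markers$time_s)
  if (any(events$time < tmin) || any(events$time > tmax))
    stop("foot-strike time outside the marker time span", call. = FALSE)
  x_fast <- if (fast_side == "left") markers$ANK_L_x else markers$ANK_R_x
  x_slow <- if (fast_side == "left") markers$ANK_R_x else markers$ANK_L_x
  xf <- stats::approx(markers$time_s, x_fast, xout = events$time)$y
  xs <- stats::approx(markers$time_s, x_slow, xout = events$time)$y
  lead <- ifelse(events$leg == "fast", xf, xs)
  trail <- ifelse(events$leg == "fast", xs, xf)
  len <- abs(lead - trail)
  lf <- len[events$leg == "fast"]
  ls <- len[events$leg == "slow"]
  n <- min(length(lf), length(ls))
  out <- data.frame(step = seq_len(n),
                    step_length_fast_m = lf[seq_len(n)],
                    step_length_slow_m = ls[seq_len(n)])
  ok <- out$step_length_fast_m + out$step_length_slow_m > 0
  out$sla <- NA_real_
  out$sla[ok] <- sla(out$step_length_fast_m[ok], out$step_length_slow_m[ok])
  class(out) <- c("step_series", "data.frame")
  out
}

#' Centre-of-mass kinematics from total ground reaction force
#'
#' Point-mass model: acceleration is `(F_total - m g zhat) / m`; velocity is
#' the cumulative trapezoidal integral per stride, with the integration
#' constant chosen so the stride-average velocity is zero in every axis
#' (treadmill frame).
#'
#' @param forces data.frame with `time_s`, `fx`, `fy`, `fz` (total over both
#'   belts, N), uniformly sampled.
#' @param mass_kg body mass.
#' @param strides stride table from [segment_strides()].
#' @param g gravitational acceleration, m/s^2.
#' @return data.frame: time_s, stride, ax, ay, az, vx, vy, vz.
#' @export
com_kinematics <- function(forces, mass_kg, strides, g = 9.81) {
  stopifnot_scalar(mass_kg, "mass_kg", positive = TRUE)
  acc <- cbind(ax = forces$fx / mass_kg,
               ay = forces$fy / mass_kg,
               az = (forces$fz - mass_kg * g) / mass_kg)
  out <- vector("list", nrow(strides))
  for (k in seq_len(nrow(strides))) {
    sel <- forces$time_s >= strides$start[k] & forces$time_s < strides$end[k]
    if (!any(sel)) next
    if (any(!is.finite(acc[sel, ])))
      stop(sprintf("non-finite force in stride %d", k), call. = FALSE)
    tt <- forces$time_s[sel]
    v <- apply(acc[sel, , drop = FALSE], 2, function(a) {
      vv <- cumtrapz(tt, a)
      vv - mean(vv)
    })
    out[[k]] <- data.frame(time_s = tt, stride = strides$stride[k],
                           acc[sel, , drop = FALSE],
                           vx = v[, "ax"], vy = v[, "ay"], vz = v[, "az"])
  }
  do.call(rbind, out)
}

#' Instantaneous power generated by one leg
#'
#' Individual-limbs power: the dot product of the leg's ground reaction
#' force with the centre-of-mass velocity, plus the dot product of the force
#' the leg applies to its belt with the belt velocity. In the treadmill
#' frame the belt moves posteriorly (`-x`) and the force on the belt is the
#' anterior-posterior reaction `-GRF_x`, so the belt term reduces to
#' `GRF_x * belt_speed`: negative (energy absorbed) for braking forces.
#'
#' @param grf matrix/data.frame with columns `fx`, `fy`, `fz` for one leg, N.
#' @param v_com matrix/data.frame with columns `vx`, `vy`, `vz`, m/s,
#'   aligned sample-by-sample with `grf`.
#' @param belt_speed belt speed magnitude, m/s.
#' @return Numeric vector of instantaneous power, W.
#' @export
leg_power <- function(grf, v_com, belt_speed) {
  stopifnot_scalar(belt_speed, "belt_speed", positive = TRUE)
  if (nrow(grf) != nrow(v_com))
    stop("force and velocity series have different lengths", call. = FALSE)
  grf$fx * v_com$vx + grf$fy * v_com$vy + grf$fz * v_com$vz +
    grf$fx * belt_speed
}

#' Positive, negative and net work rates over one stride
#'
#' Work is the trapezoidal time integral of the positive (or negative)
#' portion of instantaneous power over the stride; segments in which the
#' power changes sign are split at the linear zero crossing, so the
#' positive/negative partition is exact for the piecewise-linear
#' interpolant. Rates divide by stride duration and body mass. By
#' construction the positive and negative rates sum to the net
#' (signed-integral) rate.
#'
#' @param power instantaneous power over the stride, W.
#' @param time_s sample times, s.
#' @param duration stride duration, s.
#' @param mass_kg body mass.
#' @return Named list: `wpos`, `wneg`, `wnet` (W/kg).
#' @export
stride_work_rates <- function(power, time_s, duration, mass_kg) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(mass_kg, "mass_kg", positive = TRUE)
  n <- length(power)
  dt <- time_s[-1L] - time_s[-n]
  p1 <- power[-n]; p2 <- power[-1L]
  area <- dt * (p1 + p2) / 2
  pos <- numeric(n - 1L)
  same <- p1 * p2 >= 0
  pos[same] <- ifelse(p1[same] + p2[same] >= 0, area[same], 0)
  # sign change: split the segment at its linear zero crossing
  cross <- !same
  if (any(cross)) {
    f <- p1[cross] / (p1[cross] - p2[cross])   # crossing fraction in (0,1)
    a1 <- p1[cross] * f * dt[cross] / 2        # area before the crossing
    a2 <- p2[cross] * (1 - f) * dt[cross] / 2  # area after the crossing
    pos[cross] <- pmax(a1, 0) + pmax(a2, 0)
  }
  wpos <- sum(pos) / duration / mass_kg
  wneg <- sum(area - pos) / duration / mass_kg
  list(wpos = wpos, wneg = wneg, wnet = wpos + wneg)
}

#' Net work rate at the end of adaptation
#'
#' Mean net work rate over the final `n_last` strides.
#'
#' @param wnet per-stride net work rate, W/kg, in stride order.
#' @param n_last number of final strides to average (default 100).
#' @return Scalar W/kg.
#' @export
net_work_rate_end <- function(wnet, n_last = 100L) {
  n <- length(wnet)
  if (n < n_last)
    stop(sprintf("series has %d strides; %d required", n, n_last),
         call. = FALSE)
  mean(wnet[(n - n_last + 1L):n])
}

#' Process a raw trial through the full chain
#'
#' Filters markers (6 Hz) and forces (20 Hz) with zero-lag 4th-order
#' Butterworth filters, detects foot strikes, segments fast-leg strides,
#' computes per-step step lengths and SLA, and per-stride/per-leg work rates
#' on the 100 Hz grid (forces decimated after filtering).
#'
#' @param trial a `raw_trial`.
#' @param cutoff_kinematics_hz,cutoff_forces_hz filter cutoffs, Hz.
#' @param filter_order Butterworth order per pass.
#' @param threshold_n,debounce_ms foot-strike detection parameters.
#' @return list: `steps` (a `step_series`), `strides` (stride work table:
#'   stride, wpos_fast, wneg_fast, wpos_slow, wneg_slow, wnet, duration_s),
#'   `events`, and the filtered signals.
#' @export
process_trial <- function(trial, cutoff_kinematics_hz = 6,
                          cutoff_forces_hz = 20, filter_order = 4L,
                          threshold_n = 20, debounce_ms = 50) {
  fs_f <- 1 / median(diff(trial$forces$time_s))
  fs_m <- 1 / median(diff(trial$markers$time_s))

  ff <- trial$forces
  for (cl in setdiff(names(ff), "time_s"))
    ff[[cl]] <- butterworth_lowpass(ff[[cl]], fs_f, cutoff_forces_hz,
                                    filter_order)
  mk <- trial$markers
  for (cl in setdiff(names(mk), "time_s"))
    mk[[cl]] <- butterworth_lowpass(mk[[cl]], fs_m, cutoff_kinematics_hz,
                                    filter_order)

  events <- detect_foot_strikes(ff$fz_fast, ff$fz_slow, fs_f,
                                threshold_n, debounce_ms)
  seg <- segment_strides(events, "fast")
  steps <- step_length_at_strike(mk, events, trial$fast_side)

  # decimate filtered forces to the marker grid for the work computation
  dec <- round(fs_f / fs_m)
  keep <- seq(1L, nrow(ff), by = dec)[seq_len(nrow(mk))]
  fd <- ff[keep, , drop = FALSE]
  total <- data.frame(time_s = fd$time_s,
                      fx = fd$fx_fast + fd$fx_slow,
                      fy = fd$fy_fast + fd$fy_slow,
                      fz = fd$fz_fast + fd$fz_slow)
  com <- com_kinematics(total, trial$mass_kg, seg$strides)

  work <- do.call(rbind, lapply(seq_len(nrow(seg$strides)), function(k) {
    sel <- com$stride == seg$strides$stride[k]
    if (sum(sel) < 3L) return(NULL)
    tt <- com$time_s[sel]
    rows <- match(tt, fd$time_s)
    v <- com[sel, c("vx", "vy", "vz")]
    dur <- seg$strides$duration_s[k]
    pf <- leg_power(data.frame(fx = fd$fx_fast[rows], fy = fd$fy_fast[rows],
                               fz = fd$fz_fast[rows]), v,
                    trial$belt_speed_fast)
    ps <- leg_power(data.frame(fx = fd$fx_slow[rows], fy = fd$fy_slow[rows],
                               fz = fd$fz_slow[rows]), v,
                    trial$belt_speed_slow)
    wf <- stride_work_rates(pf, tt, dur, trial$mass_kg)
    ws <- stride_work_rates(ps, tt, dur, trial$mass_kg)
    data.frame(stride = seg$strides$stride[k],
               wpos_fast = wf$wpos, wneg_fast = wf$wneg,
               wpos_slow = ws$wpos, wneg_slow = ws$wneg,
               wnet = wf$wnet + ws$wnet, duration_s = dur)
  }))

  list(steps = steps, strides = work, events = events,
       forces_filtered = ff, markers_filtered = mk, com = com)
}
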
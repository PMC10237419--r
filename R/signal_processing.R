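# Filtering and gait-event segmentation of raw treadmill signals.

#' Zero-lag low-pass Butterworth filter
#'
#' Designs an order-`order` Butterworth low-pass filter and applies it
#' forward and backward (zero phase lag). The signal is extended at both
#' ends by odd reflection before filtering to suppress edge transients, then
#' trimmed back to its original length. Two passes double the attenuation:
#' a sinusoid exactly at the cutoff emerges at ~0.5 amplitude.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz; must be below the Nyquist rate.
#' @param order filter order per pass (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, cutoff_hz, order = 4L) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("input signal contains NA or non-finite values", call. = FALSE)
  n <- length(x)
  if (n <= 3L * order)
    stop("signal too short for the requested filter order", call. = FALSE)
  bt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # one causal pass, started in steady state at the first sample value
  pass <- function(v) {
    as.numeric(signal::filter(bt$b, bt$a, v,
                              init.x = rep(v[1L], length(bt$b) - 1L),
                              init = rep(v[1L], length(bt$a) - 1L)))
  }
  padlen <- min(n - 1L, 9L * order)
  front <- 2 * x[1L] - x[(padlen + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xe <- c(front, x, back)
  y <- rev(pass(rev(pass(xe))))
  y[(padlen + 1L):(padlen + n)]
}

#' Detect foot strikes from per-belt vertical force
#'
#' A foot strike is the first sample at which the (filtered) vertical force
#' rises above `threshold_n` after having been below it for at least
#' `debounce_ms`. Events from the two belts are merged and sorted; if two
#' consecutive events come from the same belt the earlier duplicate is
#' dropped with a warning.
#'
#' @param fz_fast,fz_slow vertical force per belt, N.
#' @param fs sampling rate, Hz.
#' @param threshold_n rising-edge threshold, N (default 20).
#' @param debounce_ms minimum off-belt time before a new strike, ms.
#' @return data.frame of class `gait_events`: `time` (s), `leg`
#'   (`"fast"`/`"slow"`), strictly increasing, alternating legs.
#' @export
detect_foot_strikes <- function(fz_fast, fz_slow, fs, threshold_n = 20,
                                debounce_ms = 50) {
  stopifnot_scalar(threshold_n, "threshold_n", positive = TRUE)
  debounce <- max(1L, round(debounce_ms / 1000 * fs))
  one_belt <- function(fz, label) {
    below <- fz < threshold_n
    rises <- which(!below[-1L] & below[-length(below)]) + 1L
    ok <- vapply(rises, function(i) {
      lo <- max(1L, i - debounce)
      all(below[lo:(i - 1L)])
    }, logical(1))
    rises <- rises[ok]
    if (length(rises) == 0L)
      stop(sprintf("no foot strikes detected on the %s belt", label),
           call. = FALSE)
    data.frame(time = (rises - 1L) / fs, leg = label,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(one_belt(fz_fast, "fast"), one_belt(fz_slow, "slow"))
  ev <- ev[order(ev$time), , drop = FALSE]
  # repair non-alternation by dropping the earlier of a same-leg pair
  repeat {
    dup <- which(ev$leg[-1L] == ev$leg[-nrow(ev)])
    if (length(dup) == 0L) break
    warning("non-alternating foot strikes; dropping earlier duplicate",
            call. = FALSE)
    ev <- ev[-dup[1L], , drop = FALSE]
  }
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Segment gait events into strides and steps
#'
#' A stride spans consecutive ipsilateral foot strikes of the chosen leg;
#' each stride owns the (up to) two steps it contains, a step being the
#' interval between consecutive contralateral strikes.
#'
#' @param events a `gait_events` table.
#' @param leg `"fast"` or `"slow"`: the leg defining stride boundaries.
#' @return list: `strides` data.frame (stride, start, end, duration_s) and
#'   `steps` data.frame (step, time, leg, stride) where `time` is the strike
#'   that ends the step and `leg` the striking leg.
#' @export
segment_strides <- function(events, leg = c("fast", "slow")) {
  leg <- match.arg(leg)
  own <- events$time[events$leg == leg]
  if (length(own) < 2L)
    stop("need at least 2 ipsilateral foot strikes to form a stride",
         call. = FALSE)
  strides <- data.frame(stride = seq_len(length(own) - 1L),
                        start = own[-length(own)], end = own[-1L])
  strides$duration_s <- strides$end - strides$start
  in_window <- events$time > strides$start[1L] &
    events$time <= strides$end[nrow(strides)]
  st <- events[in_window, , drop = FALSE]
  st$stride <- findInterval(st$time, strides$start,
                            left.open = TRUE, rightmost.closed = FALSE)
  steps <- data.frame(step = seq_len(nrow(st)), time = st$time,
                      leg = st$leg, stride = st$stride,
                      stringsAsFactors = FALSE)
  list(strides = strides, steps = steps)
}
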
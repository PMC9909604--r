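# From triaxial channels to scalar magnitude series, movement onset and
# the uniform 500-s analysis window.

#' Construct a scalar magnitude series
#'
#' @param t Sample times in seconds.
#' @param values Non-negative magnitudes, same length as `t`.
#' @param units `"m/s^2"` for acceleration or `"rad/s"` for rotation rate.
#' @param rate Sampling rate in Hz.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(t, values, units = c("m/s^2", "rad/s"), rate) {
  units <- rlang::arg_match(units)
  if (length(t) != length(values)) {
    stop_value("t and values must have the same length")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_value("magnitudes cannot be negative")
  }
  structure(list(t = as.double(t), values = as.double(values),
                 units = units, rate = rate),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples at %g Hz, %s; mean %.3g\n",
              length(x$values), x$rate, x$units, mean(x$values)))
  invisible(x)
}

#' @export
length.scalar_series <- function(x) length(x$values)

#' Euclidean magnitude of a triaxial channel
#'
#' Collapses the three axes of the user-acceleration or rotation-rate
#' channel into one orientation-independent intensity value per sample,
#' `sqrt(x^2 + y^2 + z^2)`. Samples with a missing component are dropped
#' with a message; the magnitude of the remaining samples is unchanged
#' under any rigid re-orientation of the device axes.
#'
#' @param trace An [imu_trace()].
#' @param channel `"user_acc"` (m/s^2, gravity removed) or
#'   `"rotation_rate"` (rad/s).
#' @return A [scalar_series()].
#' @export
vector_magnitude <- function(trace, channel = c("user_acc", "rotation_rate")) {
  stopifnot(inherits(trace, "imu_trace"))
  channel <- rlang::arg_match(channel)
  cols <- switch(channel,
                 user_acc = c("ua_x", "ua_y", "ua_z"),
                 rotation_rate = c("rr_x", "rr_y", "rr_z"))
  m <- as.matrix(trace$samples[cols])
  valid <- complete.cases(m) & is.finite(rowSums(m))
  if (!any(valid)) {
    stop_value("channel %s has no valid samples", channel)
  }
  if (any(!valid)) {
    inform(sprintf("dropping %d sample(s) with missing %s components",
                   sum(!valid), channel))
  }
  scalar_series(
    t = trace$samples$t[valid],
    values = sqrt(rowSums(m[valid, , drop = FALSE]^2)),
    units = if (channel == "user_acc") "m/s^2" else "rad/s",
    rate = trace$nominal_rate)
}

moving_rms <- function(values, width_samples) {
  w <- max(1L, as.integer(width_samples))
  sq <- stats::filter(values^2, rep(1 / w, w), sides = 2)
  sq <- as.double(sq)
  # edges: extend the nearest interior value so the criterion is defined
  # over the full series
  first_ok <- which(!is.na(sq))[1]
  last_ok <- tail(which(!is.na(sq)), 1)
  sq[seq_len(first_ok - 1)] <- sq[first_ok]
  if (last_ok < length(sq)) sq[(last_ok + 1):length(sq)] <- sq[last_ok]
  sqrt(pmax(sq, 0))
}

#' Detect the onset of rhythmic movement
#'
#' Finds the earliest time at which a centred moving RMS of the magnitude
#' series (window `sustain` seconds) rises above `k` times the baseline
#' level and stays above it for at least `sustain` seconds. The baseline
#' level is the 10th percentile of the moving RMS inside the initial
#' `baseline_window`: a quantile rather than the plain window RMS so that
#' a recording of burst-like movement that starts immediately (no quiet
#' lead-in) still yields onset 0 -- between bursts the moving RMS dips to
#' the noise floor, which is what the baseline should measure. A series
#' whose baseline window is already at movement-level intensity (RMS at
#' least `min_active`, e.g. continuous ergometer cranking that begins
#' with the recording) short-circuits to onset 0, since a relative rise
#' criterion cannot trigger on a signal that never was quiet.
#'
#' @param series A [scalar_series()].
#' @param baseline_window Seconds of signal used to estimate the noise
#'   floor (default 5).
#' @param k Multiplier over the baseline level (default 3).
#' @param sustain Seconds the criterion must hold (default 2); also the
#'   moving-RMS window.
#' @param min_active Absolute intensity (same units as the series) above
#'   which the baseline window counts as already-moving (default 1
#'   m/s^2: well above wrist-sensor noise, below any deliberate arm
#'   movement).
#' @return Onset time in seconds (0 when the series is already active at
#'   the start).
#' @export
detect_onset <- function(series, baseline_window = 5, k = 3, sustain = 2,
                         min_active = 1) {
  stopifnot(inherits(series, "scalar_series"))
  n <- length(series$values)
  if (n / series$rate <= baseline_window + sustain) {
    stop_value("series shorter than baseline_window + sustain")
  }
  w_sus <- max(1L, as.integer(round(sustain * series$rate)))
  rms <- moving_rms(series$values, w_sus)
  in_baseline <- series$t <= series$t[1] + baseline_window
  if (sqrt(mean(series$values[in_baseline]^2)) >= min_active) {
    return(0)
  }
  floor_level <- quantile(rms[in_baseline], 0.10, names = FALSE)
  threshold <- k * floor_level
  above <- rms > threshold
  # earliest index i such that `above` holds over i..i+w_sus-1
  bad <- c(0, cumsum(!above))
  starts <- seq_len(n - w_sus + 1)
  ok <- starts[bad[starts + w_sus] - bad[starts] == 0]
  if (length(ok) == 0) {
    stop_onset("no sustained rise above %.3g x baseline found", k)
  }
  if (ok[1] == 1L) return(0)
  # the centred window at t[ok] spans [t - sustain/2, t + sustain/2] and the
  # rise happened inside it; report its right edge, i.e. the earliest time
  # by which the trailing `sustain` seconds were above threshold
  min(series$t[ok[1]] - series$t[1] + sustain / 2,
      series$t[n] - series$t[1])
}

#' An exercise analysis window
#'
#' Acceleration and rotation magnitude series of one subject performing one
#' exercise, trimmed to the uniform analysis duration (500 s by default:
#' the shortest execution in the standard protocol, 8 min 20 s).
#'
#' @param subject_id,exercise_id Identifiers.
#' @param acc,rot [scalar_series()] sharing the same time base.
#' @param duration Window duration in seconds.
#' @return An object of class `exercise_window`.
#' @export
exercise_window <- function(subject_id, exercise_id, acc, rot, duration = 500) {
  stopifnot(inherits(acc, "scalar_series"), inherits(rot, "scalar_series"))
  if (length(acc) != length(rot) || any(abs(acc$t - rot$t) > 1e-9)) {
    stop_value("acc and rot must share the same time base")
  }
  structure(list(subject_id = as.character(subject_id),
                 exercise_id = as.integer(exercise_id),
                 acc = acc, rot = rot, duration = duration),
            class = "exercise_window")
}

#' Trim paired magnitude series to the uniform analysis window
#'
#' Cuts both series to `[onset, onset + duration)`; the window holds
#' `round(duration * rate)` samples (10,000 at 20 Hz for 500 s) and any
#' partial final sample is dropped. Trimming is idempotent: an already
#' exactly-`duration` window with onset 0 is returned unchanged.
#'
#' @param acc,rot [scalar_series()] on a common time base.
#' @param onset Start of the window, seconds.
#' @param duration Window length, seconds (default 500).
#' @param subject_id,exercise_id Identifiers carried into the window.
#' @return An [exercise_window()].
#' @export
trim_window <- function(acc, rot, onset, duration = 500,
                        subject_id = "unknown", exercise_id = 1L) {
  stopifnot(inherits(acc, "scalar_series"), inherits(rot, "scalar_series"))
  n_out <- round(duration * acc$rate)
  start <- which(acc$t >= onset - 1e-9)[1]
  if (is.na(start)) {
    stop_value("onset %.2f s is beyond the end of the series", onset)
  }
  available <- (length(acc) - start + 1) / acc$rate
  if (length(acc) - start + 1 < n_out) {
    stop_value("need %g s after onset but only %.2f s available",
               duration, available)
  }
  idx <- start:(start + n_out - 1)
  cut <- function(s) scalar_series(s$t[idx] - s$t[start], s$values[idx],
                                   units = s$units, rate = s$rate)
  exercise_window(subject_id, exercise_id, cut(acc), cut(rot), duration)
}

#' Summary statistics of a magnitude series
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (SD/mean), maximum and minimum. The CV is reported as `NA`
#' with a warning when the mean is not positive.
#'
#' @param series A [scalar_series()] or bare numeric vector.
#' @return A one-row tibble: `mean`, `sd`, `cv`, `max`, `min`, `n`.
#' @export
summarize_series <- function(series) {
  v <- if (inherits(series, "scalar_series")) series$values else as.double(series)
  if (length(v) == 0) stop_value("cannot summarise an empty series")
  m <- mean(v)
  s <- if (length(v) > 1) sd(v) else 0
  cv <- if (m > 1e-12) s / m else {
    warn("series mean is not positive; CV undefined")
    NA_real_
  }
  tibble::tibble(mean = m, sd = s, cv = cv, max = max(v), min = min(v),
                 n = length(v))
}
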
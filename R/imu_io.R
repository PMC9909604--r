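# Reading, validating and writing smartwatch IMU CSV exports.
#
# The export format is a plain comma-separated table (dot decimal, UTF-8,
# one header row) with one row per 20 Hz sample and a fixed column order.
# Only the timestamp and the three gravity-removed user-acceleration
# channels are mandatory; rotation rate, gravity, attitude quaternion,
# magnetic field and heading are optional and may be empty.

#' Column order of the IMU CSV export
#'
#' `t` is the sample timestamp (epoch or elapsed seconds; always re-based to
#' elapsed seconds on read), `ua_*` the user acceleration in m/s^2 (gravity
#' removed), `rr_*` the rotation rate in rad/s, `g_*` the gravity direction in
#' g units, `q_*` the attitude quaternion (x, y, z, w), `m_*` the magnetic
#' field with its calibration-accuracy code `m_c`, and `heading` the compass
#' heading in degrees.
#'
#' @return Character vector of column names in file order.
#' @export
imu_csv_columns <- function() {
  c("t", "ua_x", "ua_y", "ua_z", "rr_x", "rr_y", "rr_z",
    "g_x", "g_y", "g_z", "q_x", "q_y", "q_z", "q_w",
    "m_x", "m_y", "m_z", "m_c", "heading")
}

imu_mandatory_columns <- function() c("t", "ua_x", "ua_y", "ua_z")

#' Construct an IMU trace
#'
#' An `imu_trace` bundles the sample table of one subject performing one
#' exercise with its identifiers and the nominal sampling rate. Sample times
#' are re-based to elapsed seconds since the first sample and must be
#' strictly increasing. A trace whose median inter-sample interval deviates
#' by more than 20% from `1/nominal_rate` is kept but flagged
#' (`attr(trace, "rate_flagged")`).
#'
#' @param samples Tibble or data frame with at least the columns `t`,
#'   `ua_x`, `ua_y`, `ua_z`; any other columns of [imu_csv_columns()] are
#'   carried along, missing ones are filled with `NA`.
#' @param subject_id,exercise_id Identifiers; `exercise_id` is an integer
#'   in 1..4 in the standard protocol but any positive integer is accepted.
#' @param nominal_rate Nominal sampling rate in Hz (default 20).
#' @return An object of class `imu_trace`.
#' @export
imu_trace <- function(samples, subject_id, exercise_id, nominal_rate = 20) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) {
    stop_value("an IMU trace needs at least one sample")
  }
  missing_cols <- setdiff(imu_mandatory_columns(), names(samples))
  if (length(missing_cols) > 0) {
    stop_format("missing mandatory column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(imu_csv_columns(), names(samples))) {
    samples[[col]] <- NA_real_
  }
  samples <- samples[imu_csv_columns()]
  if (anyNA(samples$t) || any(!is.finite(samples$t))) {
    stop_data("sample timestamps must be finite")
  }
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop_data("sample timestamps must be strictly increasing")
  }
  # re-base: accept epoch or elapsed seconds, always store elapsed
  samples$t <- samples$t - samples$t[1]

  quat <- samples[c("q_x", "q_y", "q_z", "q_w")]
  has_quat <- complete.cases(quat)
  if (any(has_quat)) {
    norms <- sqrt(rowSums(as.matrix(quat[has_quat, ])^2))
    if (any(abs(norms - 1) > 1e-3)) {
      warn(sprintf("%d attitude quaternion(s) deviate from unit norm by > 1e-3",
                   sum(abs(norms - 1) > 1e-3)))
    }
  }

  flagged <- FALSE
  if (nrow(samples) > 1) {
    med_dt <- median(diff(samples$t))
    flagged <- abs(med_dt - 1 / nominal_rate) > 0.2 / nominal_rate
  }
  structure(
    list(subject_id = as.character(subject_id),
         exercise_id = as.integer(exercise_id),
         samples = samples,
         nominal_rate = nominal_rate),
    rate_flagged = flagged,
    class = "imu_trace"
  )
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> subject %s, exercise %d: %d samples, %.1f s at nominal %g Hz%s\n",
              x$subject_id, x$exercise_id, nrow(x$samples),
              diff(range(x$samples$t)), x$nominal_rate,
              if (isTRUE(attr(x, "rate_flagged"))) " [rate flagged]" else ""))
  invisible(x)
}

#' Read an IMU CSV export
#'
#' Reads a comma-separated sensor export (see [imu_csv_columns()] for the
#' expected header). Columns other than the documented ones are ignored;
#' timestamps are re-based to elapsed seconds since the first sample.
#'
#' @param file Path or connection to the CSV file.
#' @param subject_id,exercise_id Identifiers attached to the trace.
#' @param nominal_rate Nominal sampling rate in Hz (default 20).
#' @return An [imu_trace()].
#' @export
read_imu_csv <- function(file, subject_id, exercise_id, nominal_rate = 20) {
  # base read.csv parses doubles with strtod (correctly rounded), so values
  # written in shortest round-trip notation are recovered bit for bit
  dat <- tryCatch(
    tibble::as_tibble(utils::read.csv(file)),
    error = function(e) stop_format("cannot parse IMU CSV: %s", conditionMessage(e))
  )
  if (nrow(dat) == 0) {
    stop_format("empty IMU CSV (no data rows)")
  }
  missing_cols <- setdiff(imu_mandatory_columns(), names(dat))
  if (length(missing_cols) > 0) {
    stop_format("IMU CSV lacks mandatory column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  dat <- dat[intersect(imu_csv_columns(), names(dat))]
  dat <- dplyr::mutate(dat, dplyr::across(dplyr::everything(), as.double))
  imu_trace(dat, subject_id, exercise_id, nominal_rate)
}

#' Write an IMU trace as CSV
#'
#' Emits the documented header and one row per sample in the fixed column
#' order; optional channels that were never observed are written as empty
#' fields. Writing then re-reading reproduces the trace field for field.
#'
#' @param trace An [imu_trace()].
#' @param file Path or connection to write to.
#' @return `file`, invisibly.
#' @export
write_imu_csv <- function(trace, file) {
  stopifnot(inherits(trace, "imu_trace"))
  if (nrow(trace$samples) == 0) {
    stop_value("refusing to write an empty trace")
  }
  readr::write_csv(trace$samples, file, na = "", progress = FALSE)
  invisible(file)
}

#' Validate an IMU trace
#'
#' A pure reporting operation: counts samples, measures duration, estimates
#' the realised sampling rate, locates gaps (inter-sample intervals longer
#' than twice the nominal period) and tallies missing values per channel.
#' The trace is flagged when the estimated rate deviates from the nominal
#' rate by more than 20% or the trace is degenerate.
#'
#' @param trace An [imu_trace()], or `NULL` / zero-row input for the
#'   degenerate report.
#' @return A list of class `trace_validation` with elements `n_samples`,
#'   `duration`, `estimated_rate`, `gaps` (tibble: `index`, `t_before`,
#'   `interval`), `na_counts`, and `flagged`.
#' @export
validate_trace <- function(trace) {
  if (is.null(trace) || nrow(trace$samples) == 0) {
    return(structure(
      list(n_samples = 0L, duration = 0, estimated_rate = NA_real_,
           gaps = tibble::tibble(index = integer(), t_before = double(),
                                 interval = double()),
           na_counts = setNames(rep(0L, length(imu_csv_columns())),
                                imu_csv_columns()),
           flagged = TRUE),
      class = "trace_validation"))
  }
  s <- trace$samples
  n <- nrow(s)
  duration <- s$t[n] - s$t[1]
  est_rate <- if (n > 1 && duration > 0) (n - 1) / duration else NA_real_
  dt <- diff(s$t)
  gap_idx <- which(dt > 2 / trace$nominal_rate)
  gaps <- tibble::tibble(index = gap_idx, t_before = s$t[gap_idx],
                         interval = dt[gap_idx])
  na_counts <- vapply(s, function(col) sum(is.na(col)), integer(1))
  flagged <- n < 2 || !is.finite(est_rate) ||
    abs(est_rate - trace$nominal_rate) > 0.2 * trace$nominal_rate
  structure(
    list(n_samples = n, duration = duration, estimated_rate = est_rate,
         gaps = gaps, na_counts = na_counts, flagged = flagged),
    class = "trace_validation")
}

#' @export
print.trace_validation <- function(x, ...) {
  cat(sprintf("<trace_validation> %d samples over %.2f s (est. %.2f Hz)%s\n",
              x$n_samples, x$duration,
              if (is.na(x$estimated_rate)) NA else x$estimated_rate,
              if (x$flagged) " [FLAGGED]" else ""))
  cat(sprintf("  gaps: %d; samples with missing user acceleration: %d\n",
              nrow(x$gaps), max(x$na_counts[c("ua_x", "ua_y", "ua_z")])))
  invisible(x)
}

#' Read a subject metadata table
#'
#' Expects columns `subject_id`, `age`, `sex`, `height_cm`, `weight_kg`,
#' `bmi`, `fasted`. When height, weight and BMI are all present, BMI must
#' agree with weight/(height/100)^2 to within 1%.
#'
#' @param file Path to the subjects CSV.
#' @return A tibble, one row per subject.
#' @export
read_subjects_csv <- function(file) {
  dat <- tibble::as_tibble(utils::read.csv(file, colClasses = c(
    subject_id = "character", age = "numeric", sex = "character",
    height_cm = "numeric", weight_kg = "numeric", bmi = "numeric",
    fasted = "logical")))
  ok <- complete.cases(dat[c("height_cm", "weight_kg", "bmi")])
  if (any(ok)) {
    expected <- dat$weight_kg[ok] / (dat$height_cm[ok] / 100)^2
    bad <- abs(dat$bmi[ok] - expected) > 0.01 * expected
    if (any(bad)) {
      stop_data("BMI inconsistent with height/weight for subject(s): %s",
                paste(dat$subject_id[ok][bad], collapse = ", "))
    }
  }
  dat
}
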
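# Epoch-based activity counts from an acceleration magnitude series.
#
# The signal is reduced to one value per non-overlapping 1-s epoch and the
# epoch values are compared against a threshold T: an epoch with value v
# contributes a "low" count when T < v <= 2T and a "medium" count when
# v > 2T; total = low + medium. Free rhythmic exercises use a per-window
# variable threshold (mean + 2 SD of the trimmed acceleration series, which
# adapts to each subject's noise level); the mechanically guided ergometer
# exercise uses a fixed 0.05 m/s^2 threshold.

#' Threshold specification for activity counting
#'
#' @param kind `"variable"` (computed from the analysis window) or
#'   `"fixed"`.
#' @param value Threshold in m/s^2, non-negative.
#' @param provenance Free-text description of how the value was obtained;
#'   mandatory for variable thresholds.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(kind = c("variable", "fixed"), value, provenance = NULL) {
  kind <- rlang::arg_match(kind)
  if (!is.finite(value) || value < 0) {
    stop_value("threshold value must be finite and >= 0")
  }
  if (kind == "variable" && is.null(provenance)) {
    stop_value("a variable threshold must record its provenance")
  }
  structure(list(kind = kind, value = value,
                 provenance = provenance %||% "fixed by protocol"),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s: %.4g m/s^2 (%s)\n",
              x$kind, x$value, x$provenance))
  invisible(x)
}

#' Variable per-window threshold: mean + 2 SD
#'
#' Computed on the same trimmed acceleration window that is subsequently
#' counted, per subject and exercise.
#'
#' @param window_acc A [scalar_series()] of acceleration magnitudes, or a
#'   bare numeric vector.
#' @return A [threshold_spec()] of kind `"variable"`.
#' @export
variable_threshold <- function(window_acc) {
  v <- if (inherits(window_acc, "scalar_series")) window_acc$values else as.double(window_acc)
  if (length(v) == 0) stop_value("cannot compute a threshold from an empty window")
  s <- if (length(v) > 1) sd(v) else 0
  threshold_spec("variable", mean(v) + 2 * s,
                 provenance = sprintf("mean + 2 SD of %d-sample window", length(v)))
}

#' Fixed threshold for continuous (ergometer) movement
#'
#' @param value Threshold in m/s^2; 0.05 by default.
#' @return A [threshold_spec()] of kind `"fixed"`.
#' @export
fixed_threshold <- function(value = 0.05) {
  threshold_spec("fixed", value)
}

#' Reduce a magnitude series to one value per epoch
#'
#' Partitions the series into consecutive non-overlapping epochs of
#' `epoch_s` seconds and reduces each complete epoch with the per-epoch
#' maximum (`"peak"`, default) or mean; a trailing partial epoch is
#' dropped.
#'
#' @param series A [scalar_series()].
#' @param epoch_s Epoch length in seconds (default 1).
#' @param reducer `"peak"` or `"mean"`.
#' @return Numeric vector of per-epoch values.
#' @export
epoch_reduce <- function(series, epoch_s = 1, reducer = c("peak", "mean")) {
  stopifnot(inherits(series, "scalar_series"))
  reducer <- rlang::arg_match(reducer)
  spe <- round(series$rate * epoch_s)
  if (spe < 1) stop_value("series rate below one sample per epoch")
  n_epochs <- length(series) %/% spe
  if (n_epochs < 1) stop_value("series shorter than one epoch")
  v <- series$values[seq_len(n_epochs * spe)]
  m <- matrix(v, nrow = spe)
  fn <- if (reducer == "peak") max else mean
  apply(m, 2, fn)
}

#' Tiered activity counts from epoch values
#'
#' With threshold T: total counts the epochs whose value exceeds T, medium
#' those exceeding 2T, and low the remainder (T, 2T]. Comparisons are
#' strict, so a constant series yields zero counts under its own variable
#' threshold.
#'
#' @param epoch_values Numeric vector of per-epoch reduced values (non-
#'   negative magnitudes).
#' @param threshold A [threshold_spec()].
#' @param epoch_s Epoch length in seconds, recorded in the result.
#' @return An object of class `activity_counts` with fields `total`,
#'   `medium`, `low`, `n_epochs`, `epoch_s`, `threshold`.
#' @export
count_activity <- function(epoch_values, threshold, epoch_s = 1) {
  stopifnot(inherits(threshold, "threshold_spec"))
  if (any(!is.finite(epoch_values))) stop_data("epoch values must be finite")
  if (any(epoch_values < 0)) stop_data("epoch values are magnitudes; none may be negative")
  T_ <- threshold$value
  total <- sum(epoch_values > T_)
  medium <- sum(epoch_values > 2 * T_)
  counts <- structure(
    list(total = as.integer(total), medium = as.integer(medium),
         low = as.integer(total - medium), n_epochs = length(epoch_values),
         epoch_s = epoch_s, threshold = threshold),
    class = "activity_counts")
  stopifnot(counts$total == counts$medium + counts$low,
            counts$total >= 0, counts$total <= counts$n_epochs)
  counts
}

#' @export
print.activity_counts <- function(x, ...) {
  cat(sprintf("<activity_counts> total %d (medium %d + low %d) of %d epochs; T = %.4g m/s^2 (%s)\n",
              x$total, x$medium, x$low, x$n_epochs,
              x$threshold$value, x$threshold$kind))
  invisible(x)
}
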
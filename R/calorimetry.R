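# Metabolic-chamber session timeline and energy-expenditure differences.
#
# A whole-room open-circuit calorimeter has an effective temporal
# resolution of ~10 minutes, so the session is modelled as contiguous
# 10-min blocks. The standard protocol is 30 min air equilibration,
# 30 min resting EE, then four exercises of 10 min each separated by
# 10-min complete rests, in a randomised exercise order: 140 min in all.

CHAMBER_BLOCK_MIN <- 10

#' Energy expenditure from oxygen consumption
#'
#' Indirect calorimetry: VO2 in mL/min is converted to L/min and
#' multiplied by the caloric equivalent 4.867 kcal per litre of O2.
#'
#' @param vo2 Oxygen consumption in mL/min (vectorised, non-negative).
#' @return Energy expenditure in kcal/min.
#' @export
ee_from_vo2 <- function(vo2) {
  if (any(!is.finite(vo2)) || any(vo2 < 0)) {
    stop_value("VO2 must be finite and non-negative")
  }
  (vo2 / 1000) * 4.867
}

#' Convert kcal/min to kJ/min (and back)
#'
#' Uses the thermochemical calorie: 1 kcal = 4.184 kJ.
#'
#' @param x Energy rate.
#' @return Converted energy rate.
#' @export
kcal_to_kj <- function(x) x * 4.184

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Construct a chamber energy-expenditure series
#'
#' @param t_min Block start times in minutes since session start; blocks
#'   must be contiguous 10-min intervals.
#' @param ee Energy expenditure per block, kJ/min.
#' @param phase Optional phase labels (see [segment_timeline()]).
#' @return A tibble of class `chamber_series`.
#' @export
chamber_series <- function(t_min, ee, phase = NA_character_) {
  if (length(t_min) != length(ee)) stop_value("t_min and ee must match in length")
  if (length(t_min) > 1 && any(diff(t_min) != CHAMBER_BLOCK_MIN)) {
    stop_data("chamber blocks must be contiguous %d-min intervals", CHAMBER_BLOCK_MIN)
  }
  out <- tibble::tibble(t_min = as.double(t_min), ee = as.double(ee),
                        phase = as.character(phase))
  class(out) <- c("chamber_series", class(out))
  out
}

#' Phase template of the standard chamber protocol
#'
#' @param order Integer permutation of 1:4 giving the randomised exercise
#'   order of the session.
#' @return Character vector of 14 phase labels, one per 10-min block.
#' @export
protocol_template <- function(order = 1:4) {
  if (is.null(order) || length(order) != 4 || !setequal(order, 1:4)) {
    stop_config("exercise order must be a permutation of 1:4")
  }
  c(rep("equilibration", 3), rep("rest", 3),
    as.vector(rbind(paste0("exercise_", order), paste0("pause_", order))))
}

#' Label a chamber series with protocol phases
#'
#' Assigns each 10-min block its phase per the standard template:
#' 30 min equilibration, 30 min rest, then for each exercise k in the
#' session's randomised order a 10-min `exercise_k` block followed by a
#' 10-min `pause_k` block (140 min total). Every block receives exactly
#' one phase; blocks beyond the template are labelled `post_protocol`.
#'
#' @param series A [chamber_series()].
#' @param order Integer permutation of 1:4 (the session's exercise order).
#' @return The series with its `phase` column filled in.
#' @export
segment_timeline <- function(series, order) {
  stopifnot(inherits(series, "chamber_series"))
  template <- protocol_template(order)
  if (nrow(series) < length(template)) {
    stop_value("series covers %d min but the protocol needs %d min",
               nrow(series) * CHAMBER_BLOCK_MIN,
               length(template) * CHAMBER_BLOCK_MIN)
  }
  series$phase <- c(template, rep("post_protocol", nrow(series) - length(template)))
  series
}

#' Exercise-versus-rest energy-expenditure differences
#'
#' For each exercise k, `delta_ee_k = ee(exercise_k) - ee(reference)`.
#' The reference is the block immediately preceding the exercise
#' (`"preceding_rest"`, default: the last 10-min rest block for the first
#' exercise of the session, the preceding pause otherwise) or the mean of
#' the initial 30-min resting phase (`"session_rest"`). Negative
#' differences are allowed.
#'
#' @param series A labelled [chamber_series()] (see [segment_timeline()]).
#' @param pairing `"preceding_rest"` or `"session_rest"`.
#' @return A list of class `energy_result`: `resting_ee` (mean of the
#'   initial resting phase, kJ/min), `exercise_ee` and `delta_ee` (named
#'   numeric vectors over exercises 1..4, kJ/min), and `pairing`.
#' @export
delta_ee <- function(series, pairing = c("preceding_rest", "session_rest")) {
  stopifnot(inherits(series, "chamber_series"))
  pairing <- rlang::arg_match(pairing)
  if (anyNA(series$phase)) stop_value("series is not fully labelled; run segment_timeline first")
  rest_idx <- which(series$phase == "rest")
  if (length(rest_idx) == 0) stop_value("no resting phase in series")
  resting <- mean(series$ee[rest_idx])
  ex_ids <- sort(as.integer(sub("^exercise_", "",
                                grep("^exercise_", series$phase, value = TRUE))))
  if (!identical(ex_ids, 1:4)) {
    stop_value("missing exercise block(s): %s",
               paste(setdiff(1:4, ex_ids), collapse = ", "))
  }
  exercise_ee <- vapply(ex_ids, function(k) {
    mean(series$ee[series$phase == paste0("exercise_", k)])
  }, double(1))
  reference <- vapply(ex_ids, function(k) {
    if (pairing == "session_rest") return(resting)
    i <- which(series$phase == paste0("exercise_", k))[1]
    series$ee[i - 1]
  }, double(1))
  structure(list(resting_ee = resting,
                 exercise_ee = setNames(exercise_ee, ex_ids),
                 delta_ee = setNames(exercise_ee - reference, ex_ids),
                 pairing = pairing),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> resting %.2f kJ/min; deltaEE (%s): %s\n",
              x$resting_ee, x$pairing,
              paste(sprintf("ex%s %.2f", names(x$delta_ee), x$delta_ee),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write a chamber CSV
#'
#' Plain CSV with columns `t_min`, `value`, `value_kind` where
#' `value_kind` is `ee_kj_min` (energy expenditure, kJ/min) or
#' `vo2_ml_min` (oxygen consumption, converted on read).
#'
#' @param file Path to the CSV.
#' @return A [chamber_series()] in kJ/min.
#' @export
read_chamber_csv <- function(file) {
  dat <- tryCatch(
    tibble::as_tibble(utils::read.csv(file, colClasses = c(
      t_min = "numeric", value = "numeric", value_kind = "character"))),
    error = function(e) stop_format("cannot parse chamber CSV: %s",
                                    conditionMessage(e))
  )
  if (nrow(dat) == 0) stop_format("empty chamber CSV")
  bad <- setdiff(unique(dat$value_kind), c("ee_kj_min", "vo2_ml_min"))
  if (length(bad) > 0) stop_format("unknown value_kind: %s", paste(bad, collapse = ", "))
  ee <- ifelse(dat$value_kind == "vo2_ml_min",
               kcal_to_kj(ee_from_vo2(dat$value)), dat$value)
  chamber_series(dat$t_min, ee)
}

#' @rdname read_chamber_csv
#' @param series A [chamber_series()].
#' @export
write_chamber_csv <- function(series, file) {
  stopifnot(inherits(series, "chamber_series"))
  readr::write_csv(tibble::tibble(t_min = series$t_min, value = series$ee,
                                  value_kind = "ee_kj_min"),
                   file, progress = FALSE)
  invisible(file)
}
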
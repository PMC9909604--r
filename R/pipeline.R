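# End-to-end orchestration: traces -> magnitudes -> onset -> 500-s window
# -> summaries -> epochs -> thresholds -> counts; chamber -> deltaEE; then
# cohort tables and movement-vs-energy associations.

#' Pipeline run configuration
#'
#' Collects every configurable analysis decision with its default:
#' onset-detector parameters, epoch length and reducer, which exercises
#' use the variable threshold (the free rhythmic ones) versus the fixed
#' ergometer threshold, the energy-expenditure pairing mode, and the
#' uniform window duration.
#'
#' @param onset_baseline_window,onset_k,onset_sustain,onset_min_active
#'   See [detect_onset()].
#' @param manual_onsets Named list of onset overrides in seconds, keyed
#'   `"<subject_id>_ex<exercise_id>"`; bypasses detection for those traces.
#' @param duration Uniform analysis window, seconds (default 500).
#' @param epoch_s Epoch length, seconds (default 1).
#' @param reducer Per-epoch reducer, `"peak"` (default) or `"mean"`.
#' @param variable_exercises Exercise ids counted under the variable
#'   mean + 2 SD threshold (default 1:3); all others use the fixed one.
#' @param fixed_threshold_value Fixed threshold, m/s^2 (default 0.05).
#' @param pairing Energy reference: `"preceding_rest"` or `"session_rest"`
#'   (see [delta_ee()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(onset_baseline_window = 5, onset_k = 3,
                       onset_sustain = 2, onset_min_active = 1,
                       manual_onsets = list(),
                       duration = 500, epoch_s = 1,
                       reducer = c("peak", "mean"),
                       variable_exercises = 1:3,
                       fixed_threshold_value = 0.05,
                       pairing = c("preceding_rest", "session_rest")) {
  reducer <- rlang::arg_match(reducer)
  pairing <- rlang::arg_match(pairing)
  if (duration <= 0 || epoch_s <= 0) {
    stop_config("duration and epoch_s must be positive")
  }
  if (fixed_threshold_value < 0) stop_config("fixed threshold must be >= 0")
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop_config("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

# acceleration and rotation magnitudes on a shared (jointly valid) time
# base; a trace without any rotation data gets a zero rotation series and
# rot_available = FALSE
paired_magnitudes <- function(trace) {
  s <- trace$samples
  ua <- as.matrix(s[c("ua_x", "ua_y", "ua_z")])
  rr <- as.matrix(s[c("rr_x", "rr_y", "rr_z")])
  rot_available <- any(complete.cases(rr))
  valid <- complete.cases(ua) & is.finite(rowSums(ua)) &
    (!rot_available | complete.cases(rr))
  if (!any(valid)) stop_value("no jointly valid acceleration samples")
  t <- s$t[valid]
  acc <- scalar_series(t, sqrt(rowSums(ua[valid, , drop = FALSE]^2)),
                       "m/s^2", trace$nominal_rate)
  rot_values <- if (rot_available) {
    sqrt(rowSums(rr[valid, , drop = FALSE]^2))
  } else {
    rep(0, sum(valid))
  }
  list(acc = acc,
       rot = scalar_series(t, rot_values, "rad/s", trace$nominal_rate),
       rot_available = rot_available)
}

# one subject x exercise: trace -> metrics + counts row
process_trace <- function(trace, config) {
  mags <- paired_magnitudes(trace)
  key <- sprintf("%s_ex%d", trace$subject_id, trace$exercise_id)
  onset <- if (!is.null(config$manual_onsets[[key]])) {
    config$manual_onsets[[key]]
  } else {
    detect_onset(mags$acc, baseline_window = config$onset_baseline_window,
                 k = config$onset_k, sustain = config$onset_sustain,
                 min_active = config$onset_min_active)
  }
  win <- trim_window(mags$acc, mags$rot, onset, duration = config$duration,
                     subject_id = trace$subject_id,
                     exercise_id = trace$exercise_id)
  acc_sum <- summarize_series(win$acc)
  rot_sum <- summarize_series(win$rot)
  epochs <- epoch_reduce(win$acc, epoch_s = config$epoch_s,
                         reducer = config$reducer)
  thr <- if (trace$exercise_id %in% config$variable_exercises) {
    variable_threshold(win$acc)
  } else {
    fixed_threshold(config$fixed_threshold_value)
  }
  counts <- count_activity(epochs, thr, epoch_s = config$epoch_s)
  tibble::tibble(
    subject_id = trace$subject_id, exercise_id = trace$exercise_id,
    onset = onset,
    acc_mean = acc_sum$mean, acc_sd = acc_sum$sd, acc_cv = acc_sum$cv,
    acc_max = acc_sum$max, acc_min = acc_sum$min,
    rot_mean = ifelse(mags$rot_available, rot_sum$mean, NA_real_),
    rot_sd = ifelse(mags$rot_available, rot_sum$sd, NA_real_),
    rot_cv = ifelse(mags$rot_available, rot_sum$cv, NA_real_),
    rot_max = ifelse(mags$rot_available, rot_sum$max, NA_real_),
    rot_min = ifelse(mags$rot_available, rot_sum$min, NA_real_),
    threshold_kind = thr$kind, threshold_value = thr$value,
    n_epochs = counts$n_epochs, total = counts$total,
    medium = counts$medium, low = counts$low)
}

metric_cohort_table <- function(per_subject, prefix, label) {
  cols <- paste0(prefix, c("mean", "sd", "cv", "max", "min"))
  dat <- per_subject[c("subject_id", "exercise_id", cols)]
  names(dat) <- c("subject_id", "exercise_id", "mean", "sd", "cv", "max", "min")
  dat <- dat[is.finite(dat$mean), ]
  if (nrow(dat) == 0) return(NULL)
  out <- cohort_summary(dat)
  out$metric <- label
  dplyr::relocate(out, "metric")
}

#' Analyse a cohort held in memory
#'
#' Runs the full movement pipeline on every trace of the cohort, the
#' energy pipeline on every chamber session (when present), and assembles
#' the cohort summary tables and the movement-versus-energy association
#' table. Traces that fail a stage (e.g. onset never detected) are skipped
#' and enumerated in `failures`; the run aborts only if every trace fails.
#'
#' @param cohort A [gen_cohort()] result, or any list with the same shape
#'   (`subjects`, `traces`, optionally `chamber` and `orders`).
#' @param config A [run_config()].
#' @return A list of class `run_report`: `per_subject`, `delta_ee`,
#'   `cohort_movement`, `cohort_counts`, `cohort_delta_ee`,
#'   `associations`, `fasted_contrast`, `failures`, `n_tests`, `config`.
#' @export
analyze_cohort <- function(cohort, config = run_config()) {
  rows <- list(); failures <- list()
  for (sid in names(cohort$traces)) {
    for (ex in seq_along(cohort$traces[[sid]])) {
      trace <- cohort$traces[[sid]][[ex]]
      if (is.null(trace)) next
      res <- tryCatch(process_trace(trace, config), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          subject_id = sid, exercise_id = ex,
          stage = paste(setdiff(class(res), c("error", "condition", "rlang_error")),
                        collapse = ","),
          message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(subject_id = character(), exercise_id = integer(),
                   stage = character(), message = character())
  if (length(rows) == 0) {
    stop_value("every trace failed processing (%d failure(s))", nrow(failures))
  }
  per_subject <- dplyr::arrange(dplyr::bind_rows(rows),
                                .data$subject_id, .data$exercise_id)

  # chamber -> per-subject deltaEE
  dee <- NULL
  have_chamber <- !is.null(cohort$chamber) && length(cohort$chamber) > 0
  if (have_chamber) {
    dee_rows <- lapply(names(cohort$chamber), function(sid) {
      series <- cohort$chamber[[sid]]
      if (anyNA(series$phase)) {
        ord <- cohort$orders[[sid]]
        if (is.null(ord)) stop_config("no exercise order for subject %s", sid)
        series <- segment_timeline(series, ord)
      }
      er <- delta_ee(series, pairing = config$pairing)
      tibble::tibble(subject_id = sid, exercise_id = as.integer(names(er$delta_ee)),
                     delta_ee = unname(er$delta_ee),
                     resting_ee = er$resting_ee)
    })
    dee <- dplyr::bind_rows(dee_rows)
  }

  cohort_movement <- dplyr::bind_rows(
    metric_cohort_table(per_subject, "acc_", "acceleration"),
    metric_cohort_table(per_subject, "rot_", "rotation_rate"))
  cohort_counts <- cohort_summary(
    per_subject[c("subject_id", "exercise_id", "total", "medium", "low",
                  "threshold_value")])

  cohort_dee <- NULL; associations <- NULL; fasted_contrast <- NULL
  n_tests <- 0L
  if (have_chamber) {
    cohort_dee <- dee |>
      dplyr::group_by(.data$exercise_id) |>
      dplyr::summarise(mean = mean(.data$delta_ee), sd = sd(.data$delta_ee),
                       cv = suppressWarnings(
                         coefficient_of_variation(mean(.data$delta_ee),
                                                  sd(.data$delta_ee))),
                       max = max(.data$delta_ee), min = min(.data$delta_ee),
                       n_subjects = dplyr::n(), .groups = "drop")

    merged <- dplyr::inner_join(per_subject, dee,
                                by = c("subject_id", "exercise_id"))
    metrics <- c(acceleration = "acc_mean", rotation_rate = "rot_mean",
                 total_counts = "total")
    assoc_rows <- list()
    for (ex in sort(unique(merged$exercise_id))) {
      sub <- merged[merged$exercise_id == ex, ]
      for (mi in seq_along(metrics)) {
        x <- sub[[metrics[mi]]]; y <- sub$delta_ee
        sp <- tryCatch(suppressWarnings(spearman_corr(x, y)),
                       error = function(e) NULL)
        lf <- tryCatch(linear_fit(x, y), error = function(e) NULL)
        assoc_rows[[length(assoc_rows) + 1]] <- tibble::tibble(
          exercise_id = ex, metric = names(metrics)[mi],
          n = length(x[is.finite(x) & is.finite(y)]),
          rho = if (is.null(sp)) NA_real_ else sp$estimate,
          rho_p = if (is.null(sp)) NA_real_ else sp$p_value,
          r = if (is.null(lf)) NA_real_ else lf$estimate,
          r_squared = if (is.null(lf)) NA_real_ else lf$r_squared,
          slope = if (is.null(lf)) NA_real_ else lf$slope,
          intercept = if (is.null(lf)) NA_real_ else lf$intercept,
          lm_p = if (is.null(lf)) NA_real_ else lf$p_value)
        n_tests <- n_tests + sum(!is.null(sp), !is.null(lf))
      }
    }
    associations <- dplyr::bind_rows(assoc_rows)

    if (!is.null(cohort$subjects) && "fasted" %in% names(cohort$subjects)) {
      fed <- dplyr::inner_join(dee, cohort$subjects[c("subject_id", "fasted")],
                               by = "subject_id")
      fc_rows <- list()
      for (ex in sort(unique(fed$exercise_id))) {
        a <- fed$delta_ee[fed$exercise_id == ex & fed$fasted]
        b <- fed$delta_ee[fed$exercise_id == ex & !fed$fasted]
        tt <- tryCatch(two_sample_ttest(a, b, paired = FALSE),
                       error = function(e) NULL)
        if (!is.null(tt)) {
          fc_rows[[length(fc_rows) + 1]] <- tibble::tibble(
            exercise_id = ex, n_fasted = length(a), n_nonfasted = length(b),
            statistic = tt$statistic, p_value = tt$p_value)
          n_tests <- n_tests + 1L
        }
      }
      fasted_contrast <- if (length(fc_rows)) dplyr::bind_rows(fc_rows) else NULL
    }
  }

  structure(list(per_subject = per_subject, delta_ee = dee,
                 cohort_movement = cohort_movement,
                 cohort_counts = cohort_counts,
                 cohort_delta_ee = cohort_dee,
                 associations = associations,
                 fasted_contrast = fasted_contrast,
                 failures = failures, n_tests = n_tests, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subject-exercise windows, %d failure(s)%s\n",
              nrow(x$per_subject), nrow(x$failures),
              if (is.null(x$delta_ee)) " [movement-only: no chamber data]" else ""))
  if (!is.null(x$associations)) {
    cat(sprintf("  %d association/contrast tests at alpha = 0.05 (uncorrected)\n",
                x$n_tests))
  }
  invisible(x)
}

#' Read an analysis input directory
#'
#' Expects the fixture layout written by [write_cohort_fixture()]:
#' `imu/<subject>_ex<k>.csv`, optionally `chamber/<subject>.csv` with
#' `sessions.yaml` (exercise orders), and optionally `subjects.csv`.
#'
#' @param in_dir Input directory.
#' @return A cohort list consumable by [analyze_cohort()].
#' @export
read_cohort_dir <- function(in_dir) {
  imu_files <- list.files(file.path(in_dir, "imu"), pattern = "_ex[0-9]+\\.csv$",
                          full.names = TRUE)
  if (length(imu_files) == 0) {
    stop_format("no IMU CSVs found under %s/imu", in_dir)
  }
  traces <- list()
  for (f in imu_files) {
    base <- sub("\\.csv$", "", basename(f))
    sid <- sub("_ex[0-9]+$", "", base)
    ex <- as.integer(sub("^.*_ex", "", base))
    traces[[sid]][[ex]] <- read_imu_csv(f, subject_id = sid, exercise_id = ex)
  }
  chamber <- NULL; orders <- NULL
  chamber_files <- list.files(file.path(in_dir, "chamber"), pattern = "\\.csv$",
                              full.names = TRUE)
  if (length(chamber_files) > 0) {
    sessions_path <- file.path(in_dir, "sessions.yaml")
    if (!file.exists(sessions_path)) {
      stop_config("chamber data present but sessions.yaml (exercise orders) is missing")
    }
    sessions <- yaml::read_yaml(sessions_path)
    orders <- setNames(lapply(sessions, function(s) as.integer(s$exercise_order)),
                       vapply(sessions, `[[`, "", "subject_id"))
    chamber <- setNames(lapply(chamber_files, read_chamber_csv),
                        sub("\\.csv$", "", basename(chamber_files)))
  }
  subjects <- NULL
  if (file.exists(file.path(in_dir, "subjects.csv"))) {
    subjects <- read_subjects_csv(file.path(in_dir, "subjects.csv"))
  }
  list(subjects = subjects, traces = traces, chamber = chamber, orders = orders)
}

signif_cols <- function(df, digits = 6) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), \(x) signif(x, digits)))
}

#' Write a run report to disk
#'
#' CSV tables are serialised at 6 significant digits; `report.json` keeps
#' full precision. `run.log` records the configuration, per-trace
#' processing status and failures, and is deterministic: re-running on
#' identical inputs reproduces every output byte for byte.
#'
#' @param report A [analyze_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      readr::write_csv(signif_cols(df), file.path(out_dir, name), progress = FALSE)
    }
  }
  per_subject <- report$per_subject
  if (!is.null(report$delta_ee)) {
    per_subject <- dplyr::left_join(per_subject, report$delta_ee,
                                    by = c("subject_id", "exercise_id"))
  }
  w(per_subject, "report.csv")
  w(report$cohort_movement, "cohort_movement.csv")
  w(report$cohort_counts, "cohort_counts.csv")
  w(report$cohort_delta_ee, "cohort_delta_ee.csv")
  w(report$associations, "associations.csv")
  w(report$fasted_contrast, "fasted_contrast.csv")

  json_body <- report[c("per_subject", "delta_ee", "cohort_movement",
                        "cohort_counts", "cohort_delta_ee", "associations",
                        "fasted_contrast", "failures", "n_tests")]
  json_body$config <- unclass(report$config)
  jsonlite::write_json(json_body, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg <- report$config
  log_lines <- c(
    "movemetrics run report",
    sprintf("package version: %s", as.character(utils::packageVersion("movemetrics"))),
    sprintf("config: duration=%gs epoch=%gs reducer=%s variable_exercises=%s fixed_threshold=%g pairing=%s",
            cfg$duration, cfg$epoch_s, cfg$reducer,
            paste(cfg$variable_exercises, collapse = ","),
            cfg$fixed_threshold_value, cfg$pairing),
    sprintf("onset: baseline_window=%gs k=%g sustain=%gs manual_overrides=%d",
            cfg$onset_baseline_window, cfg$onset_k, cfg$onset_sustain,
            length(cfg$manual_onsets)),
    sprintf("windows processed: %d; failures: %d; tests run: %d",
            nrow(report$per_subject), nrow(report$failures), report$n_tests))
  if (nrow(report$failures) > 0) {
    log_lines <- c(log_lines, "failures:",
                   sprintf("  %s ex%d [%s]: %s", report$failures$subject_id,
                           report$failures$exercise_id, report$failures$stage,
                           report$failures$message))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Run the full analysis on an input directory
#'
#' Reads the directory (see [read_cohort_dir()]), analyses it, and writes
#' the report when `out_dir` is given.
#'
#' @param in_dir Input directory.
#' @param out_dir Optional output directory for the report files.
#' @param config A [run_config()].
#' @return The [analyze_cohort()] report, invisibly when `out_dir` is set.
#' @export
run_analysis <- function(in_dir, out_dir = NULL, config = run_config()) {
  cohort <- read_cohort_dir(in_dir)
  report <- analyze_cohort(cohort, config)
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}
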
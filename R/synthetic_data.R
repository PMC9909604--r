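# Seeded generators for IMU traces, chamber series and whole cohorts with
# known ground truth, emulating the standard validation protocol: three
# free rhythmic arm exercises paced at 15 movements/min and a hand
# ergometer at 40-45 rpm, performed inside a metabolic chamber.
#
# Movement archetypes:
#  * rhythmic_burst -- one smooth raised-cosine acceleration burst per
#    metronome beat (width ~1 s), in a random 3-D direction per burst,
#    with lognormal per-burst amplitude jitter and Gaussian sensor noise
#    on every axis. Between bursts the signal is noise only.
#  * continuous_ergometer -- circular hand-crank motion: constant-rate
#    sinusoidal acceleration at cadence/60 Hz in a fixed random plane of
#    rotation, with small relative amplitude jitter. No silent periods,
#    hence a much lower coefficient of variation at equal mean.
#
# Each generated trace carries the latent noise-free magnitude signal as
# attributes "clean_acc" / "clean_rot"; cohort ground truth (expected
# activity counts, hence expected energy-expenditure increments) is a
# deterministic function of that latent signal.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic trace generator
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param rate Sampling rate, Hz (default 20).
#' @param duration Active movement duration, seconds (>= one movement
#'   period; 500 by default, the uniform analysis window).
#' @param lead_in Quiet (noise-only) seconds before the movement starts;
#'   used to exercise onset detection.
#' @param archetype `"rhythmic_burst"` (metronome-paced free exercise) or
#'   `"continuous_ergometer"` (hand crank).
#' @param movement_rate Movements per minute: the metronome rate for
#'   rhythmic bursts (15 in the standard protocol) or the crank cadence in
#'   rpm (40-45) for the ergometer.
#' @param burst_amplitude Peak acceleration of a burst, or the mean
#'   acceleration magnitude of the ergometer motion, m/s^2.
#' @param burst_width Burst width, seconds (rhythmic archetype only).
#' @param amplitude_jitter Lognormal sd of per-burst amplitudes, or the
#'   relative per-sample amplitude jitter of the ergometer.
#' @param noise_sd Gaussian sensor noise sd per acceleration axis, m/s^2.
#' @param rotation_amplitude As `burst_amplitude`, for the rotation-rate
#'   channel, rad/s.
#' @param rotation_noise_sd Sensor noise sd per rotation axis, rad/s.
#' @param subject_id,exercise_id Identifiers stamped on generated traces.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = NULL, rate = 20, duration = 500,
                             lead_in = 0,
                             archetype = c("rhythmic_burst", "continuous_ergometer"),
                             movement_rate = 15, burst_amplitude = 12,
                             burst_width = 1, amplitude_jitter = 0.3,
                             noise_sd = 0.3, rotation_amplitude = 10,
                             rotation_noise_sd = 0.15,
                             subject_id = "synthetic", exercise_id = 1L) {
  archetype <- rlang::arg_match(archetype)
  if (movement_rate <= 0) stop_value("movement_rate must be positive")
  amps <- c(burst_amplitude, rotation_amplitude, noise_sd, rotation_noise_sd,
            amplitude_jitter)
  if (any(amps < 0)) stop_value("amplitudes and noise levels must be >= 0")
  if (duration < 60 / movement_rate) {
    stop_value("duration shorter than one movement period (%.2f s)",
               60 / movement_rate)
  }
  structure(as.list(environment()), class = "generator_config")
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# movement signal (magnitude x direction) + sensor noise -> imu_trace;
# the latent noise-free magnitudes are kept as attributes
assemble_trace <- function(cfg, acc_mag, acc_dir, rot_mag, rot_dir,
                           acc_clean = acc_mag, rot_clean = rot_mag) {
  n <- length(acc_mag)
  t <- (seq_len(n) - 1) / cfg$rate
  noise <- function(sd) matrix(rnorm(3 * n, sd = sd), ncol = 3)
  ua <- acc_mag * acc_dir + noise(cfg$noise_sd)
  rr <- rot_mag * rot_dir + noise(cfg$rotation_noise_sd)
  samples <- tibble::tibble(
    t = t,
    ua_x = ua[, 1], ua_y = ua[, 2], ua_z = ua[, 3],
    rr_x = rr[, 1], rr_y = rr[, 2], rr_z = rr[, 3],
    g_x = 0, g_y = 0, g_z = -1,
    q_x = 0, q_y = 0, q_z = 0, q_w = 1)
  trace <- imu_trace(samples, cfg$subject_id, cfg$exercise_id, cfg$rate)
  attr(trace, "clean_acc") <- scalar_series(t, acc_clean, "m/s^2", cfg$rate)
  attr(trace, "clean_rot") <- scalar_series(t, rot_clean, "rad/s", cfg$rate)
  trace
}

#' Generate a metronome-paced rhythmic-burst trace
#'
#' Raised-cosine acceleration and rotation bursts centred every
#' `60/movement_rate` seconds, the first burst beginning right at the end
#' of the quiet lead-in; each burst takes a fresh random 3-D direction
#' with lognormal amplitude jitter, over Gaussian per-axis sensor noise.
#' Deterministic given `config$seed`.
#'
#' @param config A [generator_config()] with archetype `"rhythmic_burst"`.
#' @return An [imu_trace()] with attributes `clean_acc`, `clean_rot`
#'   (latent noise-free magnitudes) and `burst_centers` (seconds).
#' @export
gen_rhythmic_trace <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$archetype != "rhythmic_burst") {
    stop_value("config archetype is %s, not rhythmic_burst", config$archetype)
  }
  with_seed(config$seed, {
    cfg <- config
    period <- 60 / cfg$movement_rate
    n <- round((cfg$lead_in + cfg$duration) * cfg$rate)
    t <- (seq_len(n) - 1) / cfg$rate
    n_bursts <- floor((cfg$duration - cfg$burst_width) / period) + 1
    centers <- cfg$lead_in + cfg$burst_width / 2 + (seq_len(n_bursts) - 1) * period
    amp_acc <- cfg$burst_amplitude * exp(rnorm(n_bursts, 0, cfg$amplitude_jitter))
    amp_rot <- cfg$rotation_amplitude * exp(rnorm(n_bursts, 0, cfg$amplitude_jitter))
    dir_acc <- random_unit_vectors(n_bursts)
    dir_rot <- random_unit_vectors(n_bursts)

    # nearest burst per sample; raised cosine within +/- width/2 of it
    j <- pmin(pmax(round((t - cfg$lead_in - cfg$burst_width / 2) / period) + 1, 1),
              n_bursts)
    d <- t - centers[j]
    in_burst <- abs(d) <= cfg$burst_width / 2
    pulse <- ifelse(in_burst,
                    0.5 * (1 + cos(2 * pi * d / cfg$burst_width)), 0)
    acc_clean <- amp_acc[j] * pulse
    rot_clean <- amp_rot[j] * pulse
    trace <- assemble_trace(cfg, acc_clean, dir_acc[j, , drop = FALSE],
                            rot_clean, dir_rot[j, , drop = FALSE])
    attr(trace, "burst_centers") <- centers
    trace
  })
}

#' Generate a continuous hand-ergometer trace
#'
#' Circular crank motion at `movement_rate` rpm: sinusoidal acceleration
#' (and rotation rate) at `movement_rate/60` Hz in a fixed random plane,
#' amplitude `burst_amplitude` with relative per-sample jitter
#' `amplitude_jitter`, plus Gaussian sensor noise. The magnitude series is
#' nearly constant, so its coefficient of variation is far below that of
#' any rhythmic-burst trace at equal mean.
#'
#' @param config A [generator_config()] with archetype
#'   `"continuous_ergometer"`; `movement_rate` is the cadence in rpm.
#' @return An [imu_trace()] with `clean_acc` / `clean_rot` attributes.
#' @export
gen_continuous_trace <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$archetype != "continuous_ergometer") {
    stop_value("config archetype is %s, not continuous_ergometer", config$archetype)
  }
  with_seed(config$seed, {
    cfg <- config
    n <- round((cfg$lead_in + cfg$duration) * cfg$rate)
    t <- (seq_len(n) - 1) / cfg$rate
    phase <- 2 * pi * (cfg$movement_rate / 60) * pmax(t - cfg$lead_in, 0)
    active <- t >= cfg$lead_in

    plane <- function() {
      # random orthonormal pair spanning the plane of rotation
      q <- qr.Q(qr(matrix(rnorm(9), 3)))
      list(e1 = q[, 1], e2 = q[, 2])
    }
    circular <- function(amp, jitter) {
      p <- plane()
      a <- amp * (1 + rnorm(n, 0, jitter)) * active
      dir <- outer(cos(phase), p$e1) + outer(sin(phase), p$e2)
      list(clean = amp * active, mag = pmax(a, 0), dir = dir)
    }
    acc <- circular(cfg$burst_amplitude, cfg$amplitude_jitter)
    rot <- circular(cfg$rotation_amplitude, cfg$amplitude_jitter)
    assemble_trace(cfg, acc$mag, acc$dir, rot$mag, rot$dir,
                   acc_clean = acc$clean, rot_clean = rot$clean)
  })
}

#' Generate a chamber energy-expenditure session
#'
#' Builds the 140-min protocol timeline (30 min equilibration + 30 min
#' rest + 4 x (10 min exercise + 10 min pause)) at `resting_ee` kJ/min,
#' raises each exercise block k by `delta_truth[k]`, and adds independent
#' Gaussian noise per 10-min block. Deterministic given `seed`.
#'
#' @param resting_ee Resting energy expenditure, kJ/min.
#' @param delta_truth Length-4 numeric: true per-exercise EE increments,
#'   kJ/min (indexed by exercise id, not session position).
#' @param noise_sd Per-block Gaussian noise sd, kJ/min.
#' @param order Integer permutation of 1:4, the session's exercise order.
#' @param seed Integer seed or `NULL`.
#' @return A labelled [chamber_series()] (140 min, 14 blocks).
#' @export
gen_chamber_series <- function(resting_ee, delta_truth, noise_sd = 0,
                               order = 1:4, seed = NULL) {
  if (length(delta_truth) != 4) stop_value("delta_truth must have length 4")
  with_seed(seed, {
    template <- protocol_template(order)
    ee <- rep(resting_ee, length(template))
    for (k in 1:4) {
      ee[template == paste0("exercise_", k)] <- resting_ee + delta_truth[k]
    }
    ee <- ee + rnorm(length(ee), 0, noise_sd)
    segment_timeline(
      chamber_series(t_min = (seq_along(template) - 1) * CHAMBER_BLOCK_MIN,
                     ee = ee),
      order = order)
  })
}

#' Default subject-parameter distributions for cohort generation
#'
#' Reads the package's generator defaults file
#' (`config/generator_defaults.yaml`) and applies any overrides. The
#' defaults encode the study conditions: metronome at 15 movements/min for
#' the free exercises, ergometer cadence 40-45 rpm, and amplitude/noise
#' distributions placing per-subject acceleration means in the 1.5-3.5
#' m/s^2 range typical of slow upper-limb exercise.
#'
#' @param ... Named overrides merged (recursively) into the defaults.
#' @return A nested list of distribution parameters.
#' @export
cohort_params <- function(...) {
  path <- system.file("config", "generator_defaults.yaml",
                      package = "movemetrics", mustWork = TRUE)
  defaults <- yaml::read_yaml(path)
  utils::modifyList(defaults, rlang::list2(...))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject movement parameters from the distributions in
#' `params`, generates one IMU trace per subject and exercise (exercises
#' 1-3 rhythmic at 15/min, exercise 4 ergometer), derives each subject's
#' expected activity counts from the latent noise-free signal, sets the
#' true energy-expenditure increment of exercise k to
#' `coupling_slope * expected_counts_k` plus a subject-level Gaussian
#' deviation (`dee_sd`), and generates a matching chamber session in a
#' random exercise order.
#'
#' @param n Number of subjects (>= 2).
#' @param coupling_slope True EE increment per activity count, kJ/min per
#'   count (0 for a null cohort).
#' @param seed Integer seed or `NULL`.
#' @param fasted_fraction Fraction of subjects tested after an overnight
#'   fast (1/3 by default, as in a three-per-day chamber schedule).
#' @param exercises Subset of 1:4 for which traces are generated (all by
#'   default; a subset speeds up repeated simulation).
#' @param dee_sd Sd of the subject-level deviation of the true EE
#'   increment, kJ/min.
#' @param chamber_noise_sd Per-block chamber measurement noise, kJ/min.
#' @param params Subject-parameter distributions, see [cohort_params()].
#' @return A list of class `synthetic_cohort`: `subjects` (tibble),
#'   `traces` (`traces[[subject_id]][[exercise_id]]`), `chamber` (named
#'   list of labelled series), `orders`, and `truth` (list with
#'   `coupling_slope` and a per subject x exercise tibble of expected
#'   counts and true increments).
#' @export
gen_cohort <- function(n, coupling_slope = 0.005, seed = NULL,
                       fasted_fraction = 1 / 3, exercises = 1:4,
                       dee_sd = 0.6, chamber_noise_sd = 0.2,
                       params = cohort_params()) {
  if (n < 2) stop_value("a cohort needs n >= 2 subjects")
  if (!all(exercises %in% 1:4)) stop_value("exercises must be within 1:4")
  with_seed(seed, {
    p <- params
    ids <- sprintf("S%02d", seq_len(n))
    height <- rnorm(n, p$anthropometrics$height_mean, p$anthropometrics$height_sd)
    weight <- rnorm(n, p$anthropometrics$weight_mean, p$anthropometrics$weight_sd)
    n_fasted <- max(1L, round(n * fasted_fraction))
    subjects <- tibble::tibble(
      subject_id = ids,
      age = round(runif(n, p$anthropometrics$age_range[1],
                        p$anthropometrics$age_range[2])),
      sex = sample(c("F", "M"), n, replace = TRUE),
      height_cm = round(height, 1),
      weight_kg = round(weight, 1),
      bmi = round(weight, 1) / (round(height, 1) / 100)^2,
      fasted = seq_len(n) %in% sample(n, n_fasted))

    traces <- list()
    truth_rows <- list()
    for (i in seq_len(n)) {
      traces[[ids[i]]] <- list()
      for (ex in exercises) {
        cfg <- if (ex <= 3) {
          r <- p$rhythmic
          generator_config(
            archetype = "rhythmic_burst",
            movement_rate = r$movement_rate,
            burst_amplitude = exp(rnorm(1, r$burst_amplitude_meanlog,
                                        r$burst_amplitude_sdlog)),
            burst_width = runif(1, r$burst_width_range[1], r$burst_width_range[2]),
            amplitude_jitter = r$amplitude_jitter,
            noise_sd = runif(1, r$noise_sd_range[1], r$noise_sd_range[2]),
            rotation_amplitude = exp(rnorm(1, r$rotation_amplitude_meanlog,
                                           r$rotation_amplitude_sdlog)),
            rotation_noise_sd = r$rotation_noise_sd,
            subject_id = ids[i], exercise_id = ex)
        } else {
          e <- p$ergometer
          generator_config(
            archetype = "continuous_ergometer",
            movement_rate = runif(1, e$cadence_range_rpm[1], e$cadence_range_rpm[2]),
            burst_amplitude = max(0.5, rnorm(1, e$amplitude_mean, e$amplitude_sd)),
            amplitude_jitter = e$amplitude_jitter,
            noise_sd = e$noise_sd,
            rotation_amplitude = max(0.1, rnorm(1, e$rotation_amplitude_mean,
                                                e$rotation_amplitude_sd)),
            rotation_noise_sd = e$rotation_noise_sd,
            subject_id = ids[i], exercise_id = ex)
        }
        trace <- if (ex <= 3) gen_rhythmic_trace(cfg) else gen_continuous_trace(cfg)
        traces[[ids[i]]][[ex]] <- trace
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          subject_id = ids[i], exercise_id = ex,
          expected_total = expected_counts(trace))
      }
    }

    truth <- dplyr::bind_rows(truth_rows)
    truth$delta_truth <- coupling_slope * truth$expected_total +
      rnorm(nrow(truth), 0, dee_sd)

    chamber <- list()
    orders <- list()
    resting <- rnorm(n, p$chamber$resting_ee_mean, p$chamber$resting_ee_sd)
    for (i in seq_len(n)) {
      delta4 <- rep(0, 4)
      sub_truth <- truth[truth$subject_id == ids[i], ]
      delta4[sub_truth$exercise_id] <- sub_truth$delta_truth
      orders[[ids[i]]] <- sample(4)
      chamber[[ids[i]]] <- gen_chamber_series(resting[i], delta4,
                                              noise_sd = chamber_noise_sd,
                                              order = orders[[ids[i]]])
    }

    structure(list(
      subjects = subjects, traces = traces, chamber = chamber,
      orders = orders,
      truth = list(coupling_slope = coupling_slope,
                   resting_ee = setNames(resting, ids),
                   per_exercise = truth)),
      class = "synthetic_cohort")
  })
}

# Expected activity counts of a generated trace: the counting chain applied
# to the latent noise-free magnitude (variable threshold for rhythmic
# exercises, fixed 0.05 m/s^2 for the ergometer), a deterministic function
# of the subject's movement parameters.
expected_counts <- function(trace) {
  clean <- attr(trace, "clean_acc")
  epochs <- epoch_reduce(clean, reducer = "peak")
  thr <- if (trace$exercise_id <= 3) variable_threshold(clean) else fixed_threshold()
  count_activity(epochs, thr)$total
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, exercises {%s}, coupling slope %.4g kJ/min per count\n",
              nrow(x$subjects),
              paste(sort(unique(x$truth$per_exercise$exercise_id)), collapse = ","),
              x$truth$coupling_slope))
  invisible(x)
}

#' Write a cohort as an on-disk fixture directory
#'
#' Layout: `imu/<subject>_ex<k>.csv` (IMU exports), `chamber/<subject>.csv`,
#' `subjects.csv`, `sessions.yaml` (per-subject exercise order and fasting
#' flag) and `truth.json` (generator ground truth).
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "imu"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "chamber"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$traces)) {
    for (ex in seq_along(cohort$traces[[sid]])) {
      trace <- cohort$traces[[sid]][[ex]]
      if (is.null(trace)) next
      write_imu_csv(trace, file.path(dir, "imu", sprintf("%s_ex%d.csv", sid, ex)))
    }
  }
  for (sid in names(cohort$chamber)) {
    write_chamber_csv(cohort$chamber[[sid]], file.path(dir, "chamber", paste0(sid, ".csv")))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), progress = FALSE)
  sessions <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    sid <- cohort$subjects$subject_id[i]
    list(subject_id = sid,
         exercise_order = as.integer(cohort$orders[[sid]]),
         fasted = cohort$subjects$fasted[i])
  })
  yaml::write_yaml(sessions, file.path(dir, "sessions.yaml"))
  jsonlite::write_json(
    list(coupling_slope = cohort$truth$coupling_slope,
         resting_ee = as.list(cohort$truth$resting_ee),
         per_exercise = cohort$truth$per_exercise),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
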
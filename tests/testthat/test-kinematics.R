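test_that("magnitude is the Euclidean norm of the triaxial channel", {
  s <- tibble::tibble(t = (0:1) / 20,
                      ua_x = c(3, 0), ua_y = c(4, 0), ua_z = c(0, 0))
  acc <- vector_magnitude(imu_trace(s, "S", 1), "user_acc")
  expect_equal(acc$values, c(5, 0))
  expect_identical(acc$units, "m/s^2")
})

test_that("magnitude is invariant under rigid re-orientation of the axes", {
  set.seed(11)
  for (i in 1:5) {
    trace <- random_trace(n = 300, with_optional = FALSE)
    R <- random_rotation()
    rotated <- trace
    ua <- as.matrix(trace$samples[c("ua_x", "ua_y", "ua_z")]) %*% t(R)
    rr <- as.matrix(trace$samples[c("rr_x", "rr_y", "rr_z")]) %*% t(R)
    rotated$samples[c("ua_x", "ua_y", "ua_z")] <- as.data.frame(ua)
    rotated$samples[c("rr_x", "rr_y", "rr_z")] <- as.data.frame(rr)
    expect_equal(vector_magnitude(rotated, "user_acc")$values,
                 vector_magnitude(trace, "user_acc")$values, tolerance = 1e-9)
    expect_equal(vector_magnitude(rotated, "rotation_rate")$values,
                 vector_magnitude(trace, "rotation_rate")$values,
                 tolerance = 1e-9)
  }
})

test_that("samples with missing acceleration components are dropped with a message", {
  s <- tibble::tibble(t = (0:2) / 20, ua_x = c(3, NA, 0), ua_y = c(4, 1, 0),
                      ua_z = 0)
  expect_message(acc <- vector_magnitude(imu_trace(s, "S", 1), "user_acc"),
                 "dropping 1")
  expect_equal(acc$values, c(5, 0))
  all_na <- tibble::tibble(t = (0:2) / 20, ua_x = 1, ua_y = 1, ua_z = 1)
  expect_error(vector_magnitude(imu_trace(all_na, "S", 1), "rotation_rate"),
               class = "movemetrics_value_error")
})

test_that("onset is found at the start of rhythmic movement after a quiet lead-in", {
  for (seed in 1:3) {
    trace <- gen_rhythmic_trace(generator_config(seed = seed, lead_in = 10,
                                                 duration = 60))
    onset <- detect_onset(vector_magnitude(trace, "user_acc"))
    expect_gte(onset, 9.5)
    expect_lte(onset, 10.5)
  }
})

test_that("movement from the first sample gives onset zero", {
  trace <- gen_rhythmic_trace(generator_config(seed = 4, lead_in = 0,
                                               duration = 60))
  expect_equal(detect_onset(vector_magnitude(trace, "user_acc")), 0)
  erg <- gen_continuous_trace(generator_config(
    seed = 5, archetype = "continuous_ergometer", movement_rate = 42,
    burst_amplitude = 3.2, amplitude_jitter = 0.1, noise_sd = 0.02,
    rotation_amplitude = 1.2, rotation_noise_sd = 0.02, duration = 60))
  expect_equal(detect_onset(vector_magnitude(erg, "user_acc")), 0)
})

test_that("pure sensor noise never satisfies a high onset criterion", {
  trace <- gen_rhythmic_trace(generator_config(seed = 6, burst_amplitude = 0,
                                               rotation_amplitude = 0,
                                               duration = 60))
  expect_error(detect_onset(vector_magnitude(trace, "user_acc"), k = 10),
               class = "movemetrics_onset_error")
  short <- make_series(rep(0.1, 40))
  expect_error(detect_onset(short), class = "movemetrics_value_error")
})

test_that("trimming yields the uniform 500-s window of 10,000 samples at 20 Hz", {
  trace <- gen_rhythmic_trace(generator_config(seed = 2, duration = 720))
  acc <- vector_magnitude(trace, "user_acc")
  rot <- vector_magnitude(trace, "rotation_rate")
  win <- trim_window(acc, rot, onset = 5)
  expect_length(win$acc, 10000L)
  expect_length(win$rot, 10000L)
  expect_equal(win$acc$t[1], 0)
  expect_equal(win$acc$values, acc$values[101:10100])
})

test_that("trimming an exactly-500-s series at onset zero is the identity", {
  trace <- gen_rhythmic_trace(generator_config(seed = 3, duration = 500))
  acc <- vector_magnitude(trace, "user_acc")
  rot <- vector_magnitude(trace, "rotation_rate")
  win <- trim_window(acc, rot, onset = 0)
  expect_equal(win$acc$values, acc$values)
  again <- trim_window(win$acc, win$rot, onset = 0)
  expect_equal(again$acc, win$acc)
})

test_that("trimming fails with a diagnostic when the series is too short", {
  trace <- gen_rhythmic_trace(generator_config(seed = 3, duration = 400))
  acc <- vector_magnitude(trace, "user_acc")
  rot <- vector_magnitude(trace, "rotation_rate")
  expect_error(trim_window(acc, rot, onset = 0),
               class = "movemetrics_value_error")
  expect_error(trim_window(acc, rot, onset = 0), "400")
})

test_that("series summaries use the sample standard deviation", {
  s <- summarize_series(make_series(c(1, 2, 3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 0.5)
  expect_equal(s$max, 3)
  expect_equal(s$min, 1)

  const <- summarize_series(make_series(rep(2.5, 10)))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$max, const$min)
})

test_that("the CV is scale invariant and the summary matches a two-pass oracle", {
  set.seed(8)
  for (i in 1:5) {
    v <- abs(rnorm(100, 2, 1))
    s <- summarize_series(make_series(v))
    expect_equal(summarize_series(make_series(3.7 * v))$cv, s$cv,
                 tolerance = 1e-12)
    # brute-force two-pass oracle
    m <- sum(v) / length(v)
    ss <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(s$mean, m, tolerance = 1e-12)
    expect_equal(s$sd, ss, tolerance = 1e-12)
    expect_equal(s$cv, ss / m, tolerance = 1e-12)
  }
})

test_that("a zero-mean series reports an undefined CV with a warning", {
  expect_warning(s <- summarize_series(make_series(rep(0, 10))), "CV")
  expect_true(is.na(s$cv))
})
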
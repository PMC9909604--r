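test_that("a 500-s trace at 20 Hz has 10,000 samples and 125 bursts", {
  trace <- gen_rhythmic_trace(generator_config(seed = 1))
  expect_equal(nrow(trace$samples), 10000L)
  expect_length(attr(trace, "burst_centers"), 125L)  # 15/min over 8 1/3 min
  expect_error(gen_rhythmic_trace(generator_config(seed = 1, duration = 500,
                                                   movement_rate = 0)),
               class = "movemetrics_value_error")
})

test_that("generation is deterministic under a fixed seed", {
  a <- gen_rhythmic_trace(generator_config(seed = 77))
  b <- gen_rhythmic_trace(generator_config(seed = 77))
  c <- gen_rhythmic_trace(generator_config(seed = 78))
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
  e1 <- gen_continuous_trace(generator_config(seed = 5,
                                              archetype = "continuous_ergometer",
                                              movement_rate = 42))
  e2 <- gen_continuous_trace(generator_config(seed = 5,
                                              archetype = "continuous_ergometer",
                                              movement_rate = 42))
  expect_identical(e1$samples, e2$samples)
})

test_that("the ergometer spectrum peaks at cadence/60 Hz", {
  cfg <- generator_config(seed = 10, archetype = "continuous_ergometer",
                          movement_rate = 42, burst_amplitude = 3.2,
                          amplitude_jitter = 0.05, noise_sd = 0.02,
                          rotation_amplitude = 1.2, rotation_noise_sd = 0.02)
  trace <- gen_continuous_trace(cfg)
  x <- trace$samples$ua_x
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))[2:(n / 2)]
  freq <- (1:(n / 2 - 1)) * trace$nominal_rate / n
  expect_equal(freq[which.max(spec)], 42 / 60, tolerance = 0.02)
})

test_that("continuous motion has a far lower CV than bursty motion at equal mean", {
  erg <- gen_continuous_trace(generator_config(
    seed = 11, archetype = "continuous_ergometer", movement_rate = 42,
    burst_amplitude = 2, amplitude_jitter = 0, noise_sd = 0.02,
    rotation_amplitude = 1, rotation_noise_sd = 0.02))
  rhythmic <- gen_rhythmic_trace(generator_config(seed = 12,
                                                  burst_amplitude = 12))
  cv_erg <- summarize_series(vector_magnitude(erg, "user_acc"))$cv
  cv_rhy <- summarize_series(vector_magnitude(rhythmic, "user_acc"))$cv
  expect_lt(cv_erg, 0.1)
  expect_lt(cv_erg, cv_rhy / 5)
})

test_that("chamber construction places the true increments on the exercise blocks", {
  series <- gen_chamber_series(5.0, c(1.03, 0.86, 1.31, 1.25), noise_sd = 0,
                               order = c(2, 4, 1, 3))
  expect_equal(nrow(series), 14L)
  expect_equal(series$t_min, seq(0, 130, by = 10))
  for (k in 1:4) {
    expect_equal(series$ee[series$phase == paste0("exercise_", k)],
                 c(6.03, 5.86, 6.31, 6.25)[k])
  }
  expect_error(gen_chamber_series(5, c(1, 2)), class = "movemetrics_value_error")
})

test_that("a default cohort lands in the plausible acceleration band", {
  co <- gen_cohort(14, seed = 100)
  expect_equal(nrow(co$subjects), 14L)
  expect_length(co$traces, 14L)
  rep <- analyze_cohort(co)
  acc <- rep$cohort_movement[rep$cohort_movement$metric == "acceleration", ]
  expect_true(all(acc$avg_of_mean >= 1.5 & acc$avg_of_mean <= 3.5))
})

test_that("cohort ground truth links counts to energy increments", {
  co <- gen_cohort(5, coupling_slope = 0.004, seed = 31, dee_sd = 0,
                   exercises = 1:2)
  truth <- co$truth$per_exercise
  expect_equal(nrow(truth), 10L)
  expect_equal(truth$delta_truth, 0.004 * truth$expected_total)
  expect_true(all(truth$expected_total >= 0 &
                    truth$expected_total <= 500))
  expect_error(gen_cohort(1), class = "movemetrics_value_error")
  expect_error(gen_cohort(3, exercises = 5), class = "movemetrics_value_error")
})

test_that("fixture directories round-trip through the reader", {
  co <- gen_cohort(3, seed = 41, exercises = c(1, 4))
  dir <- withr::local_tempdir()
  write_cohort_fixture(co, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort_dir(dir)
  expect_setequal(names(back$traces), co$subjects$subject_id)
  expect_equal(back$traces[["S01"]][[1]]$samples,
               co$traces[["S01"]][[1]]$samples)
  expect_equal(back$chamber[["S02"]]$ee, co$chamber[["S02"]]$ee)
  expect_equal(back$orders[["S03"]], co$orders[["S03"]])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$coupling_slope, co$truth$coupling_slope)
})
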
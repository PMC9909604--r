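test_that("write then read reproduces a trace field for field", {
  set.seed(42)
  for (i in 1:5) {
    trace <- random_trace(n = 50 + i * 10, with_optional = i %% 2 == 0)
    f <- withr::local_tempfile(fileext = ".csv")
    write_imu_csv(trace, f)
    back <- read_imu_csv(f, trace$subject_id, trace$exercise_id,
                         trace$nominal_rate)
    expect_equal(back$samples, trace$samples)
    expect_identical(back$subject_id, trace$subject_id)
    expect_identical(back$exercise_id, trace$exercise_id)
  }
})

test_that("write-read-write is byte-identical", {
  trace <- random_trace(n = 80, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(trace, f1)
  write_imu_csv(read_imu_csv(f1, "T01", 1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("missing optional channels are written as empty fields under a full header", {
  trace <- random_trace(n = 3, seed = 1, with_optional = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(trace, f)
  lines <- readLines(f)
  expect_identical(strsplit(lines[1], ",")[[1]], imu_csv_columns())
  expect_match(lines[2], ",,,$")  # trailing optional fields empty
})

test_that("a one-sample trace writes a header plus one row", {
  trace <- random_trace(n = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(trace, f)
  expect_length(readLines(f), 2L)
})

test_that("malformed inputs raise typed errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t = 1:3 / 20, rr_x = 0, rr_y = 0, rr_z = 0), f)
  expect_error(read_imu_csv(f, "S", 1), class = "movemetrics_format_error")
  expect_error(read_imu_csv(f, "S", 1), "ua_x")

  writeLines("t,ua_x,ua_y,ua_z", f)
  expect_error(read_imu_csv(f, "S", 1), class = "movemetrics_format_error")

  bad <- tibble::tibble(t = c(0, 0.1, 0.05), ua_x = 0, ua_y = 0, ua_z = 0)
  readr::write_csv(bad, f)
  expect_error(read_imu_csv(f, "S", 1), class = "movemetrics_data_error")

  expect_error(imu_trace(tibble::tibble(t = double(), ua_x = double(),
                                        ua_y = double(), ua_z = double()),
                         "S", 1),
               class = "movemetrics_value_error")
})

test_that("timestamps are re-based to elapsed seconds", {
  epoch <- 1.7e9 + (0:9) / 20
  trace <- imu_trace(tibble::tibble(t = epoch, ua_x = 1, ua_y = 0, ua_z = 0),
                     "S", 1)
  # epoch-scale magnitudes leave ~1e-7 s of floating-point residue
  expect_equal(trace$samples$t, (0:9) / 20, tolerance = 1e-5)
})

test_that("a 10,000-row 20 Hz file loads cleanly and passes the rate check", {
  trace <- random_trace(n = 10000)
  f <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(trace, f)
  back <- read_imu_csv(f, "T01", 1)
  expect_equal(nrow(back$samples), 10000L)
  expect_false(attr(back, "rate_flagged"))
  v <- validate_trace(back)
  expect_equal(nrow(v$gaps), 0L)
  expect_gt(v$estimated_rate, 19.5)
  expect_lt(v$estimated_rate, 20.5)
  expect_false(v$flagged)
})

test_that("validation reports each injected dropout as one gap", {
  t <- c(seq(0, 5, by = 0.05), seq(6.5, 10, by = 0.05))
  trace <- imu_trace(tibble::tibble(t = t, ua_x = 1, ua_y = 0, ua_z = 0),
                     "S", 1)
  v <- validate_trace(trace)
  expect_equal(nrow(v$gaps), 1L)
  expect_equal(v$gaps$t_before, 5)
  expect_equal(v$gaps$interval, 1.5)
})

test_that("the degenerate validation report is flagged with zero samples", {
  v <- validate_trace(NULL)
  expect_equal(v$n_samples, 0L)
  expect_true(v$flagged)
})

test_that("off-unit attitude quaternions trigger a warning", {
  s <- tibble::tibble(t = (0:4) / 20, ua_x = 1, ua_y = 0, ua_z = 0,
                      q_x = 0, q_y = 0, q_z = 0, q_w = 1.01)
  expect_warning(imu_trace(s, "S", 1), "unit norm")
})

test_that("subject metadata BMI must be consistent with height and weight", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    subject_id = c("a", "b"), age = c(30, 40), sex = c("F", "M"),
    height_cm = c(171, 180), weight_kg = c(72, 80),
    bmi = c(72 / 1.71^2, 30), fasted = c(TRUE, FALSE)), f)
  expect_error(read_subjects_csv(f), class = "movemetrics_data_error")
  readr::write_csv(tibble::tibble(
    subject_id = "a", age = 30, sex = "F", height_cm = 171, weight_kg = 72,
    bmi = 72 / 1.71^2, fasted = TRUE), f)
  expect_equal(nrow(read_subjects_csv(f)), 1L)
})
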
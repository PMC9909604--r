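# Fixtures are built in code; nothing is read from disk.

# a trace with random channels and elapsed timestamps at `rate`
random_trace <- function(n = 200, rate = 20, seed = NULL,
                         with_optional = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  samples <- tibble::tibble(
    t = (seq_len(n) - 1) / rate,
    ua_x = rnorm(n), ua_y = rnorm(n), ua_z = rnorm(n),
    rr_x = rnorm(n), rr_y = rnorm(n), rr_z = rnorm(n))
  if (with_optional) {
    samples$g_x <- 0; samples$g_y <- 0; samples$g_z <- -1
    q <- matrix(rnorm(4 * n), ncol = 4)
    q <- q / sqrt(rowSums(q^2))
    samples$q_x <- q[, 1]; samples$q_y <- q[, 2]
    samples$q_z <- q[, 3]; samples$q_w <- q[, 4]
  }
  imu_trace(samples, subject_id = "T01", exercise_id = 1L, nominal_rate = rate)
}

# vector rescaled to exact first two moments
moments_vector <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  v <- rnorm(n)
  mean + sd * (v - base::mean(v)) / stats::sd(v)
}

# uniformly random rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

make_series <- function(values, rate = 20, units = "m/s^2") {
  scalar_series((seq_along(values) - 1) / rate, values, units = units,
                rate = rate)
}
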
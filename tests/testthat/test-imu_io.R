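test_that("a 30 s file at 100 Hz yields a 3000-sample recording", {
  n <- 3000
  df <- data.frame(t = (seq_len(n) - 1) / 100,
                   ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rec <- read_imu_csv(path, fs = 100, leg_length = 0.9)
  expect_s3_class(rec, "imu_recording")
  expect_equal(nrow(rec$data), 3000)
})

test_that("a missing mandatory channel is reported by name", {
  df <- data.frame(t = (0:299) / 100,
                   ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_imu_csv(path), "gz", class = "pg_input_error")
})

test_that("IMU write/read round trip preserves channel values bit-identically", {
  sim <- simulate_imu_walk(walk_profile(n_steps = 6, noise_sd = 0.3,
                                        gyro_noise_sd = 0.01, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(sim$recording, path)
  back <- read_imu_csv(path, fs = 100, leg_length = 0.9)
  for (col in c("t", "ax", "ay", "az", "gx", "gy", "gz")) {
    expect_identical(back$data[[col]], sim$recording$data[[col]], label = col)
  }
})

test_that("non-finite rows are dropped and counted, never reordered", {
  n <- 400
  df <- data.frame(t = (seq_len(n) - 1) / 100,
                   ax = rnorm(n), ay = rnorm(n), az = 9.81 + rnorm(n),
                   gx = 0, gy = 0, gz = 0)
  df$az[c(50, 200)] <- NA
  rec <- suppressMessages(imu_recording(df, fs = 100))
  expect_equal(rec$n_dropped, 2)
  expect_equal(nrow(rec$data) + rec$n_dropped, n)
  expect_true(all(diff(rec$data$t) > 0))

  df$az[100:104] <- NaN  # gap of 5 > 3 consecutive samples
  expect_error(imu_recording(df, fs = 100), "gap", class = "pg_input_error")
})

test_that("too-short, non-monotone and off-rate recordings are rejected", {
  base <- data.frame(t = (0:299) / 100, ax = 0, ay = 0, az = 9.81,
                     gx = 0, gy = 0, gz = 0)
  short <- base[1:100, ]
  expect_error(imu_recording(short, fs = 100), "too short",
               class = "pg_input_error")
  bad_t <- base
  bad_t$t[10] <- bad_t$t[12]
  expect_error(imu_recording(bad_t, fs = 100), "increasing",
               class = "pg_input_error")
  expect_error(imu_recording(base, fs = 120), "sampling interval",
               class = "pg_input_error")
})

test_that("g-unit accelerometer input is converted by 9.80665", {
  n <- 300
  df <- data.frame(t = (seq_len(n) - 1) / 100, ax = 0, ay = 0, az = 1,
                   gx = 0, gy = 0, gz = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rec <- read_imu_csv(path, accel_in_g = TRUE)
  expect_equal(rec$data$az, rep(9.80665, n))
})

test_that("reference step tables read, validate and round-trip", {
  df <- data.frame(step_index = 1:10, step_length_ref = seq(0.5, 0.68, by = 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ref <- read_reference_csv(path)
  expect_equal(nrow(ref), 10)
  expect_equal(ref$step_length_ref, df$step_length_ref)

  df_bad <- df
  df_bad$step_length_ref[3] <- -0.1
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_reference_csv(path), "positive", class = "pg_input_error")

  # out-of-order indices are restored to step order
  df_shuf <- df[sample(nrow(df)), ]
  write.csv(df_shuf, path, row.names = FALSE)
  ref2 <- read_reference_csv(path)
  expect_equal(ref2$step_index, 1:10)
})

test_that("stride table write/read round trip agrees within 1e-6", {
  sim <- simulate_imu_walk(walk_profile(n_steps = 12, seed = 3))
  tab <- estimate_gait(sim$recording, coeffs = default_coefficients("all"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stride_table(tab, path)
  lines <- readLines(path)
  expect_length(lines, nrow(tab) + 1)  # header + one row per stride
  back <- read_stride_table(path)
  # 6 significant digits bound the relative round-trip error by 5e-6
  for (col in setdiff(names(tab), c("stride_index", "zone_1", "zone_2"))) {
    expect_equal(back[[col]], tab[[col]], tolerance = 5e-6, label = col)
  }
  expect_error(write_stride_table(tab[0, ], path), "empty",
               class = "pg_input_error")
})
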
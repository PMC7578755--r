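test_that("reading the canonical CSV dialect validates units, fs and time", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(f, c(0, 0.02, 0.04), 0, 0, 1)
  rec <- read_recording(f, "p01", "left", "intact",
                        accel_dialect(fs = 50))
  expect_s3_class(rec, "accel_recording")
  expect_equal(nrow(rec$data), 3)
  expect_equal(rec$fs, 50)

  # same signal declared in m/s^2 comes back identical in g
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(f2, c(0, 0.02, 0.04), 0, 0, 9.80665)
  rec2 <- read_recording(f2, "p01", "left", "intact",
                         accel_dialect(units = "ms2", fs = 50))
  expect_equal(rec2$data[, "az"], rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(rec2$data - rec$data)), 1e-9)

  # fs inferred from the median step when undeclared
  rec3 <- read_recording(f, "p01", "left", "intact")
  expect_equal(rec3$fs, 50, tolerance = 1e-9)

  f3 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(f3, c(0, 0.02, 0.04, 0.14), 0, 0, 1)
  expect_error(read_recording(f3, "p01", "left", "intact"),
               "inconsistent sampling")

  f4 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(f4, c(0, 0.04, 0.02), 0, 0, 1)
  expect_error(read_recording(f4, "p01", "left", "intact"),
               "non-monotone")

  f5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = 0:2, ax_g = 0, ay_g = 0), f5,
                   row.names = FALSE)
  expect_error(read_recording(f5, "p01", "left", "intact"),
               "missing columns.*az_g")
})

test_that("NaN policy rejects by default and interpolates short gaps on request", {
  f <- withr::local_tempfile(fileext = ".csv")
  tm <- seq(0, 0.18, by = 0.02)
  x <- seq(0, 1, length.out = 10)
  x_na <- x; x_na[5] <- NA
  write_raw_csv(f, tm, x_na, 0, 1)
  expect_error(read_recording(f, "p01", "left", "intact"), "NaN samples")
  rec <- read_recording(f, "p01", "left", "intact",
                        accel_dialect(na_action = "interpolate"))
  expect_equal(rec$data[, "ax"], x, tolerance = 1e-9)

  # gaps longer than max_gap_s stay fatal
  x_na[4:9] <- NA
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(f2, tm, x_na, 0, 1)
  expect_error(read_recording(f2, "p01", "left", "intact",
                              accel_dialect(na_action = "interpolate",
                                            max_gap_s = 0.05)),
               "gap too long")
})

test_that("session assembly clips windows to the recording intersection", {
  mk <- function(dur, side, role, t0 = 0, fs = 10)
    make_recording(rep(0, dur * fs), 0, rep(1, dur * fs), fs = fs,
                   side = side, role = role, t0 = t0)
  s1 <- build_session(mk(300, "left", "intact"),
                      mk(300, "right", "prosthesis"),
                      task_windows("a", 10, 250))
  expect_equal(s1$windows$start_s, 10)
  expect_equal(s1$windows$end_s, 250)

  expect_message(
    s2 <- build_session(mk(200, "left", "intact"),
                        mk(300, "right", "prosthesis"),
                        task_windows("a", 150, 280)),
    "clipped")
  expect_equal(s2$windows$start_s, 150)
  expect_equal(s2$windows$end_s, 200)

  expect_error(build_session(mk(300, "left", "intact"),
                             mk(300, "left", "prosthesis"),
                             task_windows("a", 0, 100)),
               "both recordings cover the left side")
  expect_error(build_session(mk(100, "left", "intact"),
                             mk(100, "right", "prosthesis", t0 = 200),
                             task_windows("a", 0, 100)),
               "zero temporal overlap")
  # preferred arm always ends up as recording_a
  s3 <- build_session(mk(300, "right", "prosthesis"),
                      mk(300, "left", "intact"),
                      task_windows("a", 0, 100))
  expect_equal(s3$recording_a$arm_role, "intact")
  expect_equal(s3$role_map, c(left = "intact", right = "prosthesis"))
})

test_that("recording and epoch files roundtrip through their CSV dialects", {
  set.seed(42)
  rec <- make_recording(rnorm(200), rnorm(200), 1 + rnorm(200, 0, 0.1),
                        fs = 25)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f, rec$participant_id, rec$arm_side, rec$arm_role)
  expect_equal(back$fs, rec$fs, tolerance = 1e-6)
  expect_equal(back$data, rec$data, tolerance = 1e-5)

  for (rep_i in 1:5) {
    n <- sample(3:40, 1)
    ep <- make_epochs(abs(rnorm(n)), abs(rnorm(n)))
    g <- withr::local_tempfile(fileext = ".csv")
    write_epochs(ep, g)
    back <- read_epochs(g, participant_id = "p01")
    expect_equal(back$mag_arm1, ep$mag_arm1, tolerance = 1e-5)
    expect_equal(back$mag_arm2, ep$mag_arm2, tolerance = 1e-5)
    expect_identical(back$active_arm1, ep$active_arm1)
    expect_identical(back$active_arm2, ep$active_arm2)
    expect_identical(back$epoch_index, ep$epoch_index)
  }

  # small and empty series keep the header contract
  ep2 <- make_epochs(c(0.1, 0.2), c(0, 0.3))
  g2 <- withr::local_tempfile(fileext = ".csv")
  write_epochs(ep2, g2)
  expect_length(readLines(g2), 3L)
  ep0 <- make_epochs(numeric(0), numeric(0))
  g0 <- withr::local_tempfile(fileext = ".csv")
  write_epochs(ep0, g0)
  expect_length(readLines(g0), 1L)
  expect_equal(nrow(read_epochs(g0)), 0L)
})
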
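test_that("reading a plain t,x,y export parses, cleans and calibrates", {
  d <- tempfile(fileext = ".csv")
  t <- (0:9) / 15
  writeLines(c("t,x,y", sprintf("%.6f,%.3f,%.3f", t, 1:10 / 10, 2:11 / 10)), d)
  tr <- read_paw_trajectory(d)
  expect_s3_class(tr, "paw_trajectory")
  expect_equal(nrow(tr), 10)
  expect_equal(traj_rate(tr), 15)

  # a non-numeric y drops that row, with a message reporting the count
  writeLines(c("t,x,y",
               sprintf("%.6f,%.3f,%.3f", t[1:5], 1:5, 1:5),
               sprintf("%.6f,%.3f,nan", t[6], 0.6),
               sprintf("%.6f,%.3f,%.3f", t[7:10], 7:10, 7:10)), d)
  expect_message(tr <- read_paw_trajectory(d), "dropped 1 row")
  expect_equal(nrow(tr), 9)

  # pixel input is scaled linearly
  writeLines(c("t,x,y", sprintf("%.6f,%.1f,%.1f", t, rep(100, 10),
                                rep(50, 10))), d)
  tr <- read_paw_trajectory(d, calibration = calibration_spec(pixels_per_inch = 50))
  expect_equal(tr$x[1], 2.0)
  expect_equal(tr$y[1], 1.0)
})

test_that("tracker-style files with preamble junk and tabs are sniffed", {
  d <- tempfile(fileext = ".txt")
  t <- (0:19) / 30
  writeLines(c("Tracker export", "calibration: inches",
               paste("t", "x", "y", sep = "\t"),
               sprintf("%.6f\t%.4f\t%.4f", t, sin(t), cos(t))), d)
  tr <- read_paw_trajectory(d, dialect = "tracker")
  expect_equal(nrow(tr), 20)
  expect_equal(traj_rate(tr), 30)
  expect_equal(tr$x, sin(t), tolerance = 1e-4)
})

test_that("read errors are classed and informative", {
  expect_error(read_paw_trajectory(tempfile()), class = "rotakin_io_error")
  d <- tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,1,1"), d)
  expect_error(read_paw_trajectory(d), class = "rotakin_validation_error")
  writeLines(c("t,x,y", "0.2,1,1", "0.1,1,1", "0.3,1,1"), d)
  expect_error(read_paw_trajectory(d), "strictly increasing",
               class = "rotakin_validation_error")
})

test_that("write then read round-trips bit-identically", {
  for (seed in 1:3) {
    tr <- generate_trial(synthetic_params(seed = seed))$trajectory
    f <- tempfile(fileext = ".csv")
    write_paw_trajectory(tr, f)
    tr2 <- read_paw_trajectory(f)
    expect_identical(tr2$t, tr$t)
    expect_identical(tr2$x, tr$x)
    expect_identical(tr2$y, tr$y)
    expect_true(file.exists(paste0(f, ".json")))
  }
})

test_that("calibration is linear in the pixel scale", {
  d <- tempfile(fileext = ".csv")
  t <- (0:9) / 15
  px <- (1:10) * 7
  writeLines(c("t,x,y", sprintf("%.6f,%.2f,%.2f", t, px, px)), d)
  for (ppi in c(10, 50, 128)) {
    tr <- read_paw_trajectory(d, calibration = calibration_spec(pixels_per_inch = ppi))
    expect_equal(tr$x * ppi, px, tolerance = 1e-12)
  }
})

test_that("trajectory invariants are enforced", {
  expect_error(paw_trajectory(0, 1, 1), class = "rotakin_validation_error")
  expect_error(paw_trajectory(c(-1, 0), c(1, 1), c(1, 1), rate_hz = 1),
               class = "rotakin_validation_error")
  expect_error(paw_trajectory(c(0, 1, 1), rep(1, 3), rep(1, 3), rate_hz = 1),
               class = "rotakin_validation_error")
  expect_error(paw_trajectory(c(0, 1), c(1, Inf), c(1, 1), rate_hz = 1),
               class = "rotakin_validation_error")
  # nominal rate must match the actual spacing within 5%
  expect_error(paw_trajectory((0:9) / 15, 1:10, 1:10, rate_hz = 30),
               class = "rotakin_validation_error")
  # consistency with the trial record: tracking may overrun the fall by <= 1 s
  tr <- make_traj(rep(1, 31), rate_hz = 15)
  rec <- trial_record("t", "m", 1, time_to_fall = 40)
  expect_true(check_trial_consistency(tr, rec))
  rec2 <- trial_record("t", "m", 1, time_to_fall = 0.5)
  expect_error(check_trial_consistency(tr, rec2),
               class = "rotakin_validation_error")
})

test_that("resampling to the native rate is the identity", {
  tr <- make_traj(sin((0:149) / 10), rate_hz = 15)
  tr2 <- resample_trajectory(tr, 15)
  expect_equal(tr2$y, tr$y, tolerance = 1e-9)
  expect_equal(tr2$t, tr$t, tolerance = 1e-9)
})

test_that("downsampling 30 Hz to 15 Hz halves the grid and is band-limited", {
  t <- (0:299) / 30
  tr <- paw_trajectory(t, rep(1.5, 300), sin(2 * pi * 2 * t), rate_hz = 30)
  tr15 <- resample_trajectory(tr, 15)
  expect_equal(nrow(tr15), 150, tolerance = 1)
  expect_equal(median(diff(tr15$t)), 1 / 15, tolerance = 1e-12)
  # a 2 Hz component must survive downsampling with its amplitude intact
  a_in <- fft_amplitude_at(tr$y, 30, 2)
  a_out <- fft_amplitude_at(tr15$y, 15, 2)
  expect_lt(abs(a_out - a_in) / a_in, 0.01)
})

test_that("extreme upsampling warns", {
  tr <- make_traj(rnorm(30), rate_hz = 15)
  expect_warning(resample_trajectory(tr, 100), "upsampling")
})

test_that("dropout gaps are flagged, not interpolated", {
  t <- c((0:10) / 15, (16:30) / 15)
  d <- tempfile(fileext = ".csv")
  writeLines(c("t,x,y", sprintf("%.6f,%.2f,%.2f", t, seq_along(t),
                                seq_along(t))), d)
  expect_warning(tr <- read_paw_trajectory(d), "gap")
  expect_equal(nrow(tr), length(t))
})
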
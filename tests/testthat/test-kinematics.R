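test_that("differentiation handles constants, ramps and sinusoids correctly", {
  n <- 151
  ks <- differentiate(make_traj(rep(2, n)), "vertical")
  expect_true(all(ks$vel == 0) && all(ks$acc == 0))
  expect_identical(ks$speed, abs(ks$vel))

  t <- (0:(n - 1)) / 15
  ks <- differentiate(make_traj(3 * t), "vertical")
  expect_equal(ks$vel, rep(3, n), tolerance = 1e-9)
  expect_equal(max(abs(ks$acc[2:(n - 1)])), 0, tolerance = 1e-9)

  # central differences attenuate a sinusoid by sin(w dt) / (w dt)
  y <- sin(2 * pi * t)
  ks <- differentiate(make_traj(y), "vertical")
  dt <- 1 / 15
  atten <- sin(2 * pi * dt) / (2 * pi * dt)
  expect_equal(max(abs(ks$vel[2:(n - 1)])), 2 * pi * atten, tolerance = 1e-9)
})

test_that("differentiate demands a uniform time base", {
  t <- c(0, 1 / 15, 2.5 / 15, 3 / 15, 4 / 15)
  tr <- paw_trajectory(t, rep(1, 5), rep(1, 5), rate_hz = 15)
  expect_error(differentiate(tr), class = "rotakin_validation_error")
})

test_that("integration of the derivative recovers position up to O(dt^2)", {
  t <- (0:299) / 15
  y <- sin(2 * pi * 0.7 * t) + 0.3 * t
  ks <- differentiate(make_traj(y), "vertical")
  n <- length(y)
  rec <- y[1] + c(0, cumsum((ks$vel[-1] + ks$vel[-n]) / 2)) / 15
  expect_lt(max(abs(rec - y)), 0.05)
})

test_that("vertical velocity partitions by sign with zeros in neither", {
  tr <- make_traj(rep(1, 5), rate_hz = 15)
  ks <- differentiate(tr, "vertical")
  ks$vel <- c(-1, 0, 2, 0, -3)
  parts <- split_vertical(ks)
  expect_equal(parts$downward, c(-1, -3))
  expect_equal(parts$upward, 2)

  ks$vel <- c(1, 2, 3, 4, 5)
  parts <- split_vertical(ks)
  expect_length(parts$downward, 0)
  expect_match(attr(parts, "flag"), "downward")

  # halves of a symmetric sinusoid have equal mean magnitude (0.5 Hz at
  # 15 Hz samples the two half-waves at mirror-image phases)
  t <- (0:599) / 15
  ks <- differentiate(make_traj(sin(2 * pi * 0.5 * t)), "vertical")
  parts <- split_vertical(ks)
  expect_equal(abs(mean(parts$downward)), abs(mean(parts$upward)),
               tolerance = 1e-2)
  ksh <- differentiate(make_traj(rep(1, 10)), "horizontal")
  expect_error(split_vertical(ksh), class = "rotakin_validation_error")
})

test_that("per-second binning honours the tail exclusion and bin edges", {
  t <- (0:(40 * 15)) / 15
  tr <- paw_trajectory(t, rep(1, length(t)), t, rate_hz = 15)
  ks <- differentiate(tr, "vertical")
  b <- bin_per_second(ks, "median", fall_time = 40)
  expect_equal(nrow(b), 35)
  expect_equal(b$bin_start, 0:34)

  # minimum of a ramp within [k, k+1) sits at the left edge
  bmin <- bin_per_second(ks, "min", fall_time = 40)
  expect_equal(bmin$value, 0:34, tolerance = 1e-9)

  expect_error(bin_per_second(ks, "median", fall_time = 5.5),
               "too short", class = "rotakin_validation_error")

  # medians of iid uniform noise centre on 0.5
  set.seed(42)
  tru <- paw_trajectory(t, rep(1, length(t)), runif(length(t)), rate_hz = 15)
  ksu <- differentiate(tru, "vertical")
  bu <- bin_per_second(ksu, "median", fall_time = 40)
  se <- sd(bu$value) / sqrt(nrow(bu))
  expect_lt(abs(mean(bu$value) - 0.5), 3 * se)
})

test_that("outlier zeroing matches the literal 6-MAD rule", {
  expect_equal(as.numeric(zero_outliers(c(1, 1, 1, 1, 100))),
               c(1, 1, 1, 1, 0))
  v <- rep(3.3, 10)
  expect_equal(as.numeric(zero_outliers(v)), v)
  expect_equal(attr(zero_outliers(v), "n_zeroed"), 0L)

  # on a large Gaussian sample, exactly the points beyond the threshold
  # (computed independently, straight from the definition) are zeroed
  set.seed(7)
  z <- rnorm(1e4)
  out <- zero_outliers(z, threshold = 2.5)
  med <- sort(z)[c(5000, 5001)]; med <- mean(med)
  madv <- sort(abs(z - med))[c(5000, 5001)]; madv <- mean(madv)
  expected_zero <- abs(z - med) > 2.5 * madv
  expect_identical(which(as.numeric(out) == 0 & z != 0), which(expected_zero))
  expect_equal(attr(out, "n_zeroed"), sum(expected_zero))

  # sd-unit variant covers the alternative reading of the threshold
  out_sd <- zero_outliers(z, threshold = 3, unit = "sd")
  expect_equal(attr(out_sd, "n_zeroed"),
               sum(abs(z - mean(z)) > 3 * sd(z)))

  # re-applying the rule with the first pass's centre and spread is a no-op
  kept <- abs(z - med) <= 2.5 * madv
  second <- as.numeric(out)
  second[abs(second - med) > 2.5 * madv] <- 0
  expect_identical(second[kept], as.numeric(out)[kept])

  # zero MAD on non-constant data keeps the rule literal: anything off the
  # median is beyond the threshold
  v <- c(rep(1, 9), 50)
  out <- zero_outliers(v, threshold = 6)
  expect_equal(as.numeric(out), c(rep(1, 9), 0))
  # the mean-absolute-deviation reading leaves the same point alone
  out_m <- zero_outliers(v, threshold = 6, unit = "mean_ad")
  expect_equal(attr(out_m, "n_zeroed"), 0L)
})

test_that("local-regression smoothing reproduces lines and reduces noise", {
  b <- tibble::tibble(bin_start = 0:19, value = 2 + 0.5 * (0:19))
  class(b) <- c("binned_series", class(tibble::tibble()))
  sm <- smooth_binned(b, 5)
  expect_equal(sm$value, b$value, tolerance = 1e-9)

  b$value <- rep(4, 20)
  expect_equal(smooth_binned(b, 5)$value, b$value, tolerance = 1e-12)

  set.seed(3)
  truth <- sin(2 * pi * (0:39) / 40)
  b <- tibble::tibble(bin_start = 0:39, value = truth + rnorm(40, 0, 0.3))
  class(b) <- c("binned_series", class(tibble::tibble()))
  sm <- smooth_binned(b, 7)
  expect_lt(mean((sm$value - truth)^2), mean((b$value - truth)^2))

  expect_warning(smooth_binned(b[1:3, ], 9), "clipping")
})
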
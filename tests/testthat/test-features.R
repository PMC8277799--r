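test_that("approximate entropy separates regular from irregular signals", {
  t <- (0:899) / 15
  expect_warning(a0 <- approximate_entropy(rep(1, 100)), "constant")
  expect_equal(a0, 0)

  set.seed(11)
  a_sine <- approximate_entropy(sin(2 * pi * 0.5 * t))
  a_noise <- approximate_entropy(rnorm(length(t)))
  expect_lt(a_sine, a_noise)

  expect_error(approximate_entropy(c(1, 2, 3), apen_params(m = 2)),
               class = "rotakin_validation_error")
})

test_that("approximate entropy equals literal template counting", {
  # the alternating 6-point series, absolute tolerance
  u <- c(1, 2, 1, 2, 1, 2)
  got <- approximate_entropy(u, apen_params(m = 2, r = 0.5,
                                            r_type = "absolute"))
  expect_equal(got, apen_oracle(u, 2, 0.5), tolerance = 1e-12)

  # random series of varied length, m and tolerance
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    m <- sample(1:3, 1)
    u <- rnorm(n)
    r_abs <- runif(1, 0.1, 0.5) * sd(u)
    got <- approximate_entropy(u, apen_params(m = m, r = r_abs,
                                              r_type = "absolute"))
    expect_equal(got, apen_oracle(u, m, r_abs), tolerance = 1e-12)
  }
})

test_that("approximate entropy is affine-invariant with SD-relative tolerance", {
  set.seed(9)
  u <- rnorm(120)
  base <- approximate_entropy(u)
  for (ab in list(c(3, 2), c(-1, 0.05), c(100, -7))) {
    expect_equal(approximate_entropy(ab[1] + ab[2] * u), base,
                 tolerance = 1e-9)
  }
})

test_that("spectral arc length is scale-invariant, non-positive and ripple-sensitive", {
  t <- (0:149) / 15
  pulse <- exp(-((t - 5) / 0.5)^2)
  s1 <- spectral_arc_length(pulse, 15)
  expect_lte(s1, 0)
  for (c in c(0.01, 3, 1000))
    expect_equal(spectral_arc_length(c * pulse, 15), s1, tolerance = 1e-9)

  # a 4 Hz ripple raises spectral content and makes the arc longer
  rippled <- pulse + 0.1 * sin(2 * pi * 4 * t)
  expect_lt(spectral_arc_length(abs(rippled), 15), s1)

  expect_error(spectral_arc_length(rep(0, 50), 15), "no movement",
               class = "rotakin_validation_error")
  expect_error(spectral_arc_length(pulse[1:5], 15),
               class = "rotakin_validation_error")
})

test_that("spectral arc length matches a direct-DFT chord-summation oracle", {
  t <- (0:149) / 15
  signals <- list(
    exp(-((t - 5) / 0.5)^2),
    exp(-((t - 5) / 0.5)^2) + 0.1 * sin(2 * pi * 4 * t) + 0.15,
    abs(differentiate(generate_trial(synthetic_params(seed = 2))$trajectory,
                      "vertical")$speed[1:150])
  )
  for (v in signals) {
    expect_equal(spectral_arc_length(v, 15), sparc_oracle(v, 15),
                 tolerance = 1e-6)
  }
  # fixed (non-adaptive) band agrees once the oracle is given the full band
  p_fixed <- sparc_params(cutoff_hz = 7.5, amplitude_threshold = 0.05,
                          adaptive = FALSE)
  v <- signals[[2]]
  expect_equal(spectral_arc_length(v, 15, p_fixed),
               sparc_oracle(v, 15, cutoff_hz = 7.5, amp_th = -Inf),
               tolerance = 1e-6)
})

test_that("feature vectors have the documented trivial values", {
  tr <- make_traj(rep(2, 200))
  fv <- compute_features(tr, axis = "vertical")
  expect_equal(fv$variance_pos, 0)
  expect_equal(fv$mad_pos, 0)
  expect_equal(fv$apen_pos, 0)
  expect_equal(fv$mean_vel, 0)

  t <- (0:150) / 15
  fv <- compute_features(paw_trajectory(t, rep(1, 151), t, rate_hz = 15),
                         axis = "vertical")
  expect_equal(fv$mean_pos, 5.0, tolerance = 1e-6)
  expect_equal(fv$mean_vel, 1.0, tolerance = 1e-9)
  expect_equal(fv$mean_speed, 1.0, tolerance = 1e-9)
  expect_equal(fv$variance_pos, 100 / 12, tolerance = 0.02)
})

test_that("the full catalog matches a straight-line recomputation", {
  tr <- generate_trial(synthetic_params(skill = 0.1, seed = 1))$trajectory
  fv <- compute_features(tr, axis = "vertical")
  y <- tr$y
  n <- length(y)
  dt <- 1 / 15
  vel <- c((y[2] - y[1]) / dt,
           (y[3:n] - y[1:(n - 2)]) / (2 * dt),
           (y[n] - y[n - 1]) / dt)
  acc <- c((vel[2] - vel[1]) / dt,
           (vel[3:n] - vel[1:(n - 2)]) / (2 * dt),
           (vel[n] - vel[n - 1]) / dt)
  expect_equal(fv$mean_pos, sum(y) / n, tolerance = 1e-12)
  expect_equal(fv$mean_vel, mean(vel), tolerance = 1e-12)
  expect_equal(fv$mean_speed, mean(abs(vel)), tolerance = 1e-12)
  expect_equal(fv$mean_acc, mean(acc), tolerance = 1e-12)
  expect_equal(fv$variance_pos, sum((y - mean(y))^2) / n, tolerance = 1e-12)
  expect_equal(fv$mad_pos, median(abs(y - median(y))), tolerance = 1e-12)
  expect_equal(fv$apen_pos, apen_oracle(y, 2, 0.2 * sd(y)), tolerance = 1e-9)
  expect_equal(fv$sparc_speed, sparc_oracle(abs(vel), 15), tolerance = 1e-6)
  expect_equal(fv$sparc_acc, sparc_oracle(abs(acc), 15), tolerance = 1e-6)
})

test_that("feature vectors are deterministic", {
  tr <- generate_trial(synthetic_params(seed = 6))$trajectory
  expect_identical(compute_features(tr), compute_features(tr))
})

test_that("first-T windows behave as windows", {
  t <- (0:(16 * 15)) / 15
  tr <- paw_trajectory(t, rep(1, length(t)), t, rate_hz = 15)
  expect_equal(first_t_feature(tr, "vertical", "mean_speed", 16), 1,
               tolerance = 1e-9)

  # at the full duration the windowed value is the whole-trial value
  tr2 <- generate_trial(synthetic_params(skill = 0.1, seed = 3))$trajectory
  full <- compute_features(tr2, axis = "vertical")$apen_pos
  expect_equal(first_t_feature(tr2, "vertical", "apen_pos",
                               traj_duration(tr2)), full)

  # a signal that turns irregular after 20 s scores lower in its first 16 s
  t <- (0:(45 * 15)) / 15
  set.seed(2)
  y <- sin(2 * pi * t) + ifelse(t > 20, rnorm(length(t), 0, 1), 0)
  tr3 <- paw_trajectory(t, rep(1, length(t)), y, rate_hz = 15)
  early <- first_t_feature(tr3, "vertical", "apen_pos", 16)
  whole <- compute_features(tr3, axis = "vertical")$apen_pos
  expect_lt(early, whole)

  expect_error(first_t_feature(tr3, "vertical", "apen_pos", 100),
               class = "rotakin_validation_error")
  expect_error(first_t_feature(tr3, "vertical", "apen_pos", 4),
               class = "rotakin_validation_error")
})

test_that("feature tables bind cohort metadata to per-trial rows", {
  co <- simulate_cohort(3, seed = 8)
  ft <- feature_table(co, axis = "vertical")
  expect_equal(nrow(ft), 3)
  expect_true(all(c("mouse_id", "time_to_fall", "apen_pos") %in% names(ft)))
})
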
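#' Accelerating-rod schedule
#'
#' The standard accelerating protocol: the rod starts at 4 RPM and gains
#' 1 RPM every 8 s up to a 40 RPM plateau (reached at 288 s).
#'
#' @param v0 Initial speed, RPM.
#' @param step Increment per interval, RPM.
#' @param step_interval Seconds between increments.
#' @param v_max Plateau speed, RPM.
#' @return A list of class `rod_schedule`.
#' @export
rod_schedule <- function(v0 = 4, step = 1, step_interval = 8, v_max = 40) {
  if (v0 <= 0 || step < 0 || step_interval <= 0 || v_max < v0)
    abort("invalid rod schedule", class = "rotakin_validation_error")
  structure(list(v0 = v0, step = step, step_interval = step_interval,
                 v_max = v_max), class = "rod_schedule")
}

#' Rod speed at time t
#'
#' Discrete stepwise convention: the speed holds for each `step_interval` and
#' jumps at its end, so `rpm_at(s, 8) == 5` under the default schedule.
#' Non-decreasing and bounded by `[v0, v_max]` for all `t >= 0`.
#'
#' @param schedule A [rod_schedule()].
#' @param t Time(s) in seconds, >= 0. Vectorized.
#' @param ramp Use a continuous linear ramp instead of discrete steps
#'   (sensitivity analysis; default FALSE).
#' @return Speed(s) in RPM.
#' @export
#' @examples
#' rpm_at(rod_schedule(), c(0, 8, 600))
rpm_at <- function(schedule, t, ramp = FALSE) {
  if (any(t < 0))
    abort("t must be non-negative", class = "rotakin_validation_error")
  inc <- if (ramp) t / schedule$step_interval else t %/% schedule$step_interval
  pmin(schedule$v0 + inc * schedule$step, schedule$v_max)
}

#' Synthetic trajectory parameters
#'
#' Controls the statistical structure of simulated paw trajectories. `skill`
#' drives the fall hazard (better mice stay on longer). `vertical_jitter` is
#' the SD of the multiplicative phase noise on the stepping cadence: 0 gives
#' a strictly periodic saw-tooth (minimal vertical approximate entropy),
#' larger values give increasingly irregular stepping. `horizontal_regularity`
#' in \[0, 1\] sets how evenly stance adjustments are spaced (1 = strictly
#' periodic, low horizontal approximate entropy; 0 = Poisson timing, high).
#' `tremor_amp` scales a 5.5 Hz ripple superimposed on the stepping, the
#' smoothness dial: more ripple makes the speed spectrum ragged and the
#' spectral arc length more negative. `learning_delta` is the fractional
#' reduction of jitter, tremor and slip rate applied per later trial (trials
#' 2 and 3) to emulate one-trial motor learning.
#'
#' @param skill In \[0, 1\].
#' @param vertical_jitter Phase-noise SD, >= 0 (default 0.3).
#' @param horizontal_regularity In \[0, 1\] (default 0.5).
#' @param slip_rate Downward slip events per second (default 0.05).
#' @param slip_depth Slip dip depth in inches (default 0.35).
#' @param noise_sd Additive measurement noise in inches (default 0.02).
#' @param tremor_amp Ripple amplitude in inches (default 0.05).
#' @param learning_delta Per-trial fractional change in \[0, 1) (default 0).
#' @param seed RNG seed; a fixed seed fixes the output exactly.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(skill = 0.5, vertical_jitter = 0.3,
                             horizontal_regularity = 0.5, slip_rate = 0.05,
                             slip_depth = 0.35, noise_sd = 0.02,
                             tremor_amp = 0.05, learning_delta = 0,
                             seed = 1) {
  stopifnot_param <- function(ok, msg)
    if (!ok) abort(msg, class = "rotakin_validation_error")
  stopifnot_param(skill >= 0 && skill <= 1, "skill must be in [0, 1]")
  stopifnot_param(vertical_jitter >= 0, "vertical_jitter must be >= 0")
  stopifnot_param(horizontal_regularity >= 0 && horizontal_regularity <= 1,
                  "horizontal_regularity must be in [0, 1]")
  stopifnot_param(slip_rate >= 0 && slip_depth >= 0 && noise_sd >= 0 &&
                    tremor_amp >= 0, "rates and amplitudes must be >= 0")
  stopifnot_param(learning_delta >= 0 && learning_delta < 1,
                  "learning_delta must be in [0, 1)")
  structure(list(skill = skill, vertical_jitter = vertical_jitter,
                 horizontal_regularity = horizontal_regularity,
                 slip_rate = slip_rate, slip_depth = slip_depth,
                 noise_sd = noise_sd, tremor_amp = tremor_amp,
                 learning_delta = learning_delta, seed = seed),
            class = "synthetic_params")
}

# per-second Bernoulli fall hazard from the 30 s floor, capped at 300 s
draw_fall_time <- function(params, schedule, floor_s = 30, cap_s = 300) {
  for (k in floor_s:(cap_s - 1)) {
    h <- stats::plogis(-8 + 0.5 * rpm_at(schedule, k) - 14 * params$skill)
    if (runif(1) < h) return(k + runif(1))
  }
  cap_s
}

#' Simulate one rotarod trial
#'
#' Generates a paw trajectory with the phenomenology of a mouse on an
#' accelerating rod. The vertical trace is a quasi-periodic saw-tooth: the
#' paw is carried slowly down with the rod surface and rapidly re-placed,
#' with cadence proportional to rod speed, phase jitter, a high-frequency
#' tremor ripple, occasional downward slip dips, and additive measurement
#' noise. The horizontal trace is a baseline stance position with lagged
#' step adjustments whose timing regularity is controlled by
#' `horizontal_regularity`. The fall time is drawn from a per-second hazard
#' increasing with rod speed and decreasing with skill, floored at 30 s and
#' capped at 300 s. Deterministic given `params$seed`.
#'
#' @param params A [synthetic_params()].
#' @param schedule A [rod_schedule()].
#' @param rate_hz Sampling rate, default 15.
#' @param mouse_id,trial_index,group Metadata for the [trial_record()].
#' @return A list with elements `trajectory` ([paw_trajectory()]) and
#'   `record` ([trial_record()]).
#' @export
generate_trial <- function(params, schedule = rod_schedule(), rate_hz = 15,
                           mouse_id = "m1", trial_index = 1,
                           group = NA_character_) {
  set.seed(params$seed)
  fall <- draw_fall_time(params, schedule)
  dt <- 1 / rate_hz
  n <- floor(fall * rate_hz) + 1
  t <- (0:(n - 1)) * dt
  rpm <- rpm_at(schedule, t)

  # vertical: saw-tooth stepping phase-locked to the rod
  cadence <- 0.8 + 0.05 * rpm
  eps <- if (params$vertical_jitter > 0)
    rnorm(n, 0, params$vertical_jitter) else numeric(n)
  dphi <- 2 * pi * cadence * dt * (1 + eps)
  phase <- cumsum(dphi)
  # saw-tooth with a finite re-placement phase: the paw is carried down with
  # the rod surface for 80% of the cycle, then re-placed over the last 20%
  u <- (phase / (2 * pi)) %% 1
  step_y <- 0.6 * ifelse(u < 0.8, 1 - u / 0.8, (u - 0.8) / 0.2)
  tremor <- if (params$tremor_amp > 0)
    params$tremor_amp * sin(2 * pi * 5.5 * t + runif(1, 0, 2 * pi))
  else numeric(n)
  slips <- numeric(n)
  n_slip <- stats::rpois(1, params$slip_rate * fall)
  if (n_slip > 0) {
    ts <- sort(runif(n_slip, 0, fall))
    for (s in ts) slips <- slips + params$slip_depth * exp(-((t - s) / 0.15)^2)
  }
  noise_y <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else numeric(n)
  y <- 0.8 + step_y + tremor - slips + noise_y

  # horizontal: oscillatory stance sway whose timing regularity is set by
  # horizontal_regularity (1 = strictly periodic adjustments, 0 = heavily
  # phase-jittered)
  reg <- params$horizontal_regularity
  sway_hz <- 0.5
  eps_x <- if (reg < 1) rnorm(n, 0, 2 * (1 - reg)) else numeric(n)
  phase_x <- cumsum(2 * pi * sway_hz * dt * (1 + eps_x))
  noise_x <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else numeric(n)
  x <- 1.5 + 0.25 * sin(phase_x) + noise_x

  trial_id <- sprintf("%s_t%d", mouse_id, trial_index)
  list(trajectory = paw_trajectory(t, x, y, trial_id = trial_id,
                                   rate_hz = rate_hz),
       record = trial_record(trial_id, mouse_id, trial_index,
                             time_to_fall = fall, group = group))
}

#' Default cohort parameter sampler
#'
#' Draws per-mouse parameters implementing the constructions the analysis
#' stages are validated against: skill uniform on \[0, 1\];
#' `vertical_jitter` increasing with skill (so vertical approximate entropy
#' rises with time-to-fall); `horizontal_regularity` equal to skill (so
#' horizontal approximate entropy falls with time-to-fall); slip rate
#' decreasing with skill.
#'
#' @param learning_delta Passed through to every mouse (default 0).
#' @return A function of `(mouse_index)` returning a [synthetic_params()]
#'   (drawing from the current RNG stream).
#' @export
default_params_sampler <- function(learning_delta = 0) {
  function(mouse_index) {
    skill <- runif(1)
    synthetic_params(
      skill = skill,
      vertical_jitter = 0.05 + 0.9 * skill,
      horizontal_regularity = skill,
      slip_rate = 0.08 * (1 - skill),
      learning_delta = learning_delta,
      seed = sample.int(.Machine$integer.max - 1, 1))
  }
}

# apply the learning effect to smoothness-relevant parameters for trial k
apply_learning <- function(params, trial_index) {
  f <- (1 - params$learning_delta)^(trial_index - 1)
  params$vertical_jitter <- params$vertical_jitter * f
  params$tremor_amp <- params$tremor_amp * f
  params$slip_rate <- params$slip_rate * f
  params
}

#' Simulate a cohort of mice
#'
#' Draws per-mouse parameters from `params_sampler` and generates
#' `trial_count` trials per mouse. Trials 2 and 3 apply the mouse's
#' `learning_delta` (reduced jitter, tremor and slip rate: smoother, more
#' regular movement), emulating one-trial motor learning. Reproducible by
#' `seed`.
#'
#' @param n_mice Number of mice, >= 2.
#' @param trial_count Trials per mouse, 1 to 3.
#' @param params_sampler Function of mouse index returning a
#'   [synthetic_params()]; default [default_params_sampler()].
#' @param seed Cohort seed.
#' @param group Group label recorded for every trial.
#' @param rate_hz Sampling rate, default 15.
#' @param schedule A [rod_schedule()].
#' @return A tibble with one row per trial: `mouse_id`, `trial_id`,
#'   `trial_index`, `time_to_fall`, `group`, `skill`, and a `trajectory`
#'   list-column.
#' @export
simulate_cohort <- function(n_mice, trial_count = 1,
                            params_sampler = default_params_sampler(),
                            seed = 1, group = NA_character_, rate_hz = 15,
                            schedule = rod_schedule()) {
  if (n_mice < 2)
    abort("n_mice must be >= 2", class = "rotakin_validation_error")
  if (!trial_count %in% 1:3)
    abort("trial_count must be 1, 2 or 3",
          class = "rotakin_validation_error")
  set.seed(seed)
  mice <- lapply(seq_len(n_mice), params_sampler)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                   n_mice * trial_count),
                        n_mice, trial_count)
  rows <- list()
  for (i in seq_len(n_mice)) {
    for (k in seq_len(trial_count)) {
      p <- apply_learning(mice[[i]], k)
      p$seed <- trial_seeds[i, k]
      tr <- generate_trial(p, schedule = schedule, rate_hz = rate_hz,
                           mouse_id = sprintf("m%02d", i), trial_index = k,
                           group = group)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tr$record,
        tibble::tibble(skill = mice[[i]]$skill, trajectory = list(tr$trajectory)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate an early/late class dataset with a programmed offset
#'
#' Builds the classifier's input directly: 20 early and 20 late one-second
#' feature observations, each feature standard normal within class, with the
#' first feature's late-class mean shifted by `offset_sd` within-class
#' standard deviations. `offset_sd = 0` gives identically distributed
#' classes (the null the AUC-0.5 interpretation rests on); `offset_sd = 6`
#' gives the strongly separated case.
#'
#' @param offset_sd Mean shift of feature 1 in within-class SDs.
#' @param n_features Number of feature columns, 1 to 6 (default 6).
#' @param seed RNG seed.
#' @return A `class_dataset` tibble (standardized columns).
#' @export
simulate_class_dataset <- function(offset_sd = 6, n_features = 6, seed = 1) {
  if (n_features < 1 || n_features > 6)
    abort("n_features must be in 1..6", class = "rotakin_validation_error")
  set.seed(seed)
  nm <- paste0("f", seq_len(n_features))
  early <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(20 * n_features), 20)), nm))
  late <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(20 * n_features), 20)), nm))
  late[[1]] <- late[[1]] + offset_sd
  class_dataset_from_bins(early, late)
}

#' Write a synthetic cohort to disk in the formats the reader accepts
#'
#' Emits one trajectory CSV per trial (the tidy `trial_id,t,x,y` dialect
#' [read_paw_trajectory()] parses) plus a cohort manifest CSV.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    write_paw_trajectory(cohort$trajectory[[i]],
                         file.path(dir, paste0(cohort$trial_id[i], ".csv")),
                         sidecar = FALSE)
  }
  manifest <- dplyr::select(cohort, -dplyr::any_of("trajectory"))
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
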
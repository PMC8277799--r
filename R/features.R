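#' Parameters for approximate entropy
#'
#' Approximate entropy (ApEn) measures the regularity of a time series: a
#' periodic trace (sine, saw-tooth stepping) scores low, an irregular trace
#' scores high. The defaults m = 2, r = 0.2 SD are the classic choices used
#' throughout the rodent-gait and physiological-signal literature.
#'
#' @param m Embedding (template) length, >= 1. Default 2.
#' @param r Match tolerance. With `r_type = "sd_fraction"` (default) the
#'   tolerance is `r` times the series standard deviation, making ApEn
#'   invariant to affine rescaling of the series; with `"absolute"` it is
#'   used as-is.
#' @param r_type `"sd_fraction"` or `"absolute"`.
#' @return A list of class `apen_params`.
#' @export
apen_params <- function(m = 2, r = 0.2, r_type = c("sd_fraction", "absolute")) {
  r_type <- match.arg(r_type)
  if (m < 1) abort("m must be >= 1", class = "rotakin_validation_error")
  if (r <= 0 || (r_type == "sd_fraction" && r >= 1))
    abort("r must be in (0, 1) as an SD fraction, or positive when absolute",
          class = "rotakin_validation_error")
  structure(list(m = m, r = r, r_type = r_type), class = "apen_params")
}

#' Approximate entropy of a scalar series
#'
#' Standard Pincus ApEn: `Phi_m - Phi_{m+1}`, where `Phi_m` is the mean log
#' fraction of length-`m` templates lying within the tolerance of each
#' template under the Chebyshev (maximum-coordinate) distance, self-matches
#' included.
#'
#' @param series Numeric vector, length > `m + 1`.
#' @param params An [apen_params()].
#' @return A non-negative scalar. A constant series returns 0 with a warning
#'   (zero spread admits no meaningful tolerance).
#' @export
#' @examples
#' t <- (0:899) / 15
#' approximate_entropy(sin(2 * pi * 0.5 * t)) # low: regular
approximate_entropy <- function(series, params = apen_params()) {
  n <- length(series)
  if (n <= params$m + 1)
    abort(sprintf("series of length %d too short for m = %d", n, params$m),
          class = "rotakin_validation_error")
  s <- sd(series)
  if (s == 0) {
    if (params$r_type == "sd_fraction") {
      warn("constant series: approximate entropy is 0")
      return(0)
    }
  }
  tol <- if (params$r_type == "sd_fraction") params$r * s else params$r
  if (tol == 0) {
    warn("zero tolerance on constant series: approximate entropy is 0")
    return(0)
  }
  apen_cpp(as.numeric(series), as.integer(params$m), tol)
}

#' Parameters for spectral arc length
#'
#' Spectral arc length (SPARC) scores movement smoothness as the negated arc
#' length of the normalized magnitude spectrum of a speed profile: smoother
#' movement concentrates spectral power at low frequency, giving a shorter
#' trace and a value closer to zero. Defaults follow the human-movement
#' smoothness literature: 10 Hz maximum cutoff with an adaptive extension to
#' the highest frequency whose normalized magnitude exceeds 0.05.
#'
#' @param cutoff_hz Maximum frequency (Hz) of the arc integration band.
#' @param amplitude_threshold Normalized magnitude floor for the adaptive
#'   cutoff, in (0, 1).
#' @param zero_pad_to FFT length; default next power of 2 >= 4x the signal
#'   length.
#' @param adaptive Use the adaptive cutoff rule (default) or the fixed
#'   `[0, cutoff_hz]` band.
#' @return A list of class `sparc_params`.
#' @export
sparc_params <- function(cutoff_hz = 10, amplitude_threshold = 0.05,
                         zero_pad_to = NULL, adaptive = TRUE) {
  if (cutoff_hz <= 0)
    abort("cutoff_hz must be positive", class = "rotakin_validation_error")
  if (amplitude_threshold <= 0 || amplitude_threshold >= 1)
    abort("amplitude_threshold must be in (0, 1)",
          class = "rotakin_validation_error")
  structure(list(cutoff_hz = cutoff_hz,
                 amplitude_threshold = amplitude_threshold,
                 zero_pad_to = zero_pad_to, adaptive = adaptive),
            class = "sparc_params")
}

#' Spectral arc length (SPARC) movement smoothness
#'
#' Computes the magnitude spectrum of the speed profile by zero-padded FFT,
#' normalizes it by its maximum, restricts it to the band from 0 Hz to the
#' smaller of `cutoff_hz` and (adaptively) the highest frequency whose
#' normalized magnitude exceeds `amplitude_threshold`, and returns the
#' negated arc length of the (normalized frequency, normalized magnitude)
#' curve. Always <= 0; closer to zero is smoother. Scale-invariant:
#' `SPARC(c * v) == SPARC(v)` for c > 0.
#'
#' @param speed_series Numeric vector (the speed magnitude profile), length
#'   >= 8, not all zero.
#' @param rate_hz Sampling rate of the series in Hz.
#' @param params A [sparc_params()].
#' @return A non-positive scalar.
#' @export
spectral_arc_length <- function(speed_series, rate_hz, params = sparc_params()) {
  n <- length(speed_series)
  if (n < 8)
    abort("speed series must have at least 8 samples",
          class = "rotakin_validation_error")
  if (all(speed_series == 0))
    abort("no movement: speed series is identically zero",
          class = "rotakin_validation_error")
  nfft <- params$zero_pad_to %||% 2^ceiling(log2(4 * n))
  if (nfft < n) abort("zero_pad_to must be >= the series length",
                      class = "rotakin_validation_error")
  spec <- Mod(fft(c(speed_series, rep(0, nfft - n))))
  half <- seq_len(floor(nfft / 2) + 1)
  freq <- (half - 1) * rate_hz / nfft
  mag <- spec[half] / max(spec[half])
  fc <- min(params$cutoff_hz, rate_hz / 2)
  sel <- which(freq <= fc)
  f_sel <- freq[sel]; m_sel <- mag[sel]
  if (params$adaptive) {
    above <- which(m_sel >= params$amplitude_threshold)
    keep <- seq(above[1], above[length(above)])
    f_sel <- f_sel[keep]; m_sel <- m_sel[keep]
  }
  f_range <- f_sel[length(f_sel)] - f_sel[1]
  if (f_range == 0) return(0)
  -sum(sqrt((diff(f_sel) / f_range)^2 + diff(m_sel)^2))
}

#' Intra-session feature vector for one trial and axis
#'
#' Computes the full catalog of intra-session kinematic features from the
#' (resampled) trajectory: mean position, signed mean velocity and
#' acceleration, mean absolute speed, population variance and unscaled median
#' absolute deviation of position, approximate entropy of position, and
#' spectral arc length of the absolute speed and acceleration-magnitude
#' profiles (negated arc lengths; closer to zero is smoother). Features are
#' computed over the whole trial or over the first `t_max` seconds.
#'
#' @param traj A [paw_trajectory()]; resampled to `resample_hz` when its rate
#'   differs.
#' @param axis `"vertical"`, `"horizontal"`, or both (the default computes
#'   one row per axis).
#' @param t_max Optional window end in seconds: features use samples with
#'   `t < t_max` only. `NULL` means the full trial.
#' @param apen An [apen_params()].
#' @param sparc A [sparc_params()].
#' @param resample_hz Common analysis rate, default 15 Hz.
#' @param sparc_signed Score SPARC on signed velocity instead of absolute
#'   speed (sensitivity analysis; default FALSE).
#' @return A tibble with one row per axis: `trial_id`, `axis`, `window`,
#'   `t_max`, and the feature columns `mean_pos`, `mean_vel`, `mean_speed`,
#'   `mean_acc`, `variance_pos`, `mad_pos`, `apen_pos`, `sparc_speed`,
#'   `sparc_acc`.
#' @export
compute_features <- function(traj, axis = c("vertical", "horizontal"),
                             t_max = NULL, apen = apen_params(),
                             sparc = sparc_params(), resample_hz = 15,
                             sparc_signed = FALSE) {
  axis <- match.arg(axis, several.ok = TRUE)
  if (abs(traj_rate(traj) - resample_hz) > 1e-9)
    traj <- resample_trajectory(traj, resample_hz)
  if (!is.null(t_max)) {
    if (t_max > traj_duration(traj) + 1e-9)
      abort(sprintf("window of %g s exceeds the trial duration of %.2f s",
                    t_max, traj_duration(traj)),
            class = "rotakin_validation_error")
  }
  purrr::map_dfr(axis, function(ax) {
    ks <- differentiate(traj, ax)
    if (!is.null(t_max)) ks <- ks[ks$t - ks$t[1] <= t_max + 1e-12, ]
    pos <- ks$pos
    n <- length(pos)
    sp <- if (sparc_signed) ks$vel else ks$speed
    acc_mag <- abs(ks$acc)
    tibble::tibble(
      trial_id = traj_id(traj),
      axis = ax,
      window = if (is.null(t_max)) "full_trial" else "first_T_seconds",
      t_max = t_max %||% NA_real_,
      mean_pos = mean(pos),
      mean_vel = mean(ks$vel),
      mean_speed = mean(ks$speed),
      mean_acc = mean(ks$acc),
      variance_pos = mean((pos - mean(pos))^2),
      mad_pos = mad(pos, constant = 1),
      apen_pos = if (sd(pos) == 0) 0 else approximate_entropy(pos, apen),
      sparc_speed = if (all(sp == 0)) NA_real_ else
        spectral_arc_length(sp, traj_rate(traj), sparc),
      sparc_acc = if (all(acc_mag == 0)) NA_real_ else
        spectral_arc_length(acc_mag, traj_rate(traj), sparc)
    )
  })
}

#' Single feature over the first T seconds of a trial
#'
#' The early-segment building block of the cumulative predictor scan: one
#' named catalog feature computed on samples with `t < t_max` only.
#'
#' @param traj A [paw_trajectory()].
#' @param axis `"vertical"` or `"horizontal"`.
#' @param feature One of the [compute_features()] column names, e.g.
#'   `"apen_pos"`.
#' @param t_max Window end in seconds; at least 8 (the first rod-speed
#'   increment) and at most the trial duration.
#' @param ... Passed to [compute_features()].
#' @return A scalar.
#' @export
first_t_feature <- function(traj, axis, feature, t_max, ...) {
  if (t_max < 8)
    abort("the cumulative-segment scan starts at 8 s; t_max must be >= 8",
          class = "rotakin_validation_error")
  fv <- compute_features(traj, axis = axis, t_max = t_max, ...)
  if (!feature %in% names(fv))
    abort(sprintf("unknown feature '%s'", feature),
          class = "rotakin_validation_error")
  fv[[feature]][1]
}

#' Feature table for a cohort
#'
#' Maps [compute_features()] over a cohort tibble (one row per trial with a
#' `trajectory` list-column, as produced by [simulate_cohort()]) and binds
#' the per-trial metadata to the feature rows.
#'
#' @param cohort Tibble with columns `trajectory` (list of
#'   [paw_trajectory()]) plus metadata (`mouse_id`, `trial_index`,
#'   `time_to_fall`, `group`, ...).
#' @param ... Passed to [compute_features()] (e.g. `axis`, `t_max`).
#' @return A tibble: metadata columns joined to one feature row per trial and
#'   axis.
#' @export
feature_table <- function(cohort, ...) {
  meta <- dplyr::select(tibble::as_tibble(cohort), -dplyr::any_of("trajectory"))
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    dplyr::bind_cols(meta[i, ],
                     dplyr::select(compute_features(cohort$trajectory[[i]], ...),
                                   -dplyr::any_of("trial_id")))
  })
}
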
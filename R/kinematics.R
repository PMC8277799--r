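#' Derive per-axis kinematics from a trajectory
#'
#' Computes signed velocity and acceleration for one axis by central finite
#' differences (one-sided at the ends), together with absolute speed.
#' Negative vertical velocity means downward paw motion. The trajectory must
#' be on a uniform time base; resample first.
#'
#' @param traj A [paw_trajectory()] on a uniform time base.
#' @param axis `"vertical"` (y) or `"horizontal"` (x).
#' @return A tibble of class `kinematic_series` with columns `t`, `pos`,
#'   `vel`, `speed`, `acc`, and attributes `axis`, `rate_hz`, `trial_id`.
#' @export
#' @examples
#' tr <- paw_trajectory((0:149) / 15, x = rep(1.5, 150), y = sin(2 * pi * (0:149) / 15))
#' ks <- differentiate(tr, "vertical")
#' head(ks)
differentiate <- function(traj, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  dts <- diff(traj$t)
  dt <- 1 / traj_rate(traj)
  if (max(abs(dts - dt)) > 1e-9)
    abort("trajectory time base is not uniform; resample_trajectory() first",
          class = "rotakin_validation_error")
  pos <- if (axis == "vertical") traj$y else traj$x
  vel <- central_diff(pos, dt)
  acc <- central_diff(vel, dt)
  out <- tibble::tibble(t = traj$t, pos = pos, vel = vel,
                        speed = abs(vel), acc = acc)
  attr(out, "axis") <- axis
  attr(out, "rate_hz") <- traj_rate(traj)
  attr(out, "trial_id") <- traj_id(traj)
  class(out) <- c("kinematic_series", class(tibble::tibble()))
  out
}

# second-order central difference, first-order one-sided at the ends
central_diff <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Partition vertical velocity into downward and upward components
#'
#' Negative vertical velocity indicates downward movement. Zero-velocity
#' samples are assigned to neither component. If one component is empty the
#' result carries a `flag` attribute naming it.
#'
#' @param series A vertical `kinematic_series`.
#' @return A list with signed numeric vectors `downward` (all < 0) and
#'   `upward` (all > 0).
#' @export
split_vertical <- function(series) {
  if (!identical(attr(series, "axis"), "vertical"))
    abort("split_vertical requires a vertical-axis series",
          class = "rotakin_validation_error")
  down <- series$vel[series$vel < 0]
  up <- series$vel[series$vel > 0]
  out <- list(downward = down, upward = up)
  if (length(down) == 0 || length(up) == 0)
    attr(out, "flag") <- paste0("no ", if (length(down) == 0) "downward" else "upward",
                                " samples")
  out
}

#' Bin a kinematic quantity into one-second intervals
#'
#' Summarizes a per-sample quantity into contiguous half-open one-second bins
#' `[k, k+1)` counted from trial start. The last `tail_exclusion_s` seconds
#' before the fall are omitted so that values from a falling mouse do not
#' contaminate the series, and any partial trailing bin is dropped.
#'
#' @param series A `kinematic_series` (or any tibble with `t` and the chosen
#'   variable).
#' @param stat Per-bin statistic: `"median"`, `"min"`, `"variance"` or
#'   `"mean"`.
#' @param fall_time Trial time-to-fall in seconds.
#' @param tail_exclusion_s Seconds excluded before the fall (default 5).
#' @param var Which column to bin (default `"pos"`).
#' @return A tibble of class `binned_series` with columns `bin_start`
#'   (integer seconds) and `value`, and attributes `feature_name`,
#'   `excluded_tail_s`.
#' @export
bin_per_second <- function(series, stat = c("median", "min", "variance", "mean"),
                           fall_time, tail_exclusion_s = 5, var = "pos") {
  stat <- match.arg(stat)
  if (fall_time > series$t[nrow(series)] - series$t[1] + 1)
    abort("fall_time exceeds series duration by more than 1 s",
          class = "rotakin_validation_error")
  usable <- fall_time - tail_exclusion_s
  if (usable < 1)
    abort("trial too short to bin: fall_time minus tail exclusion is under 1 s",
          class = "rotakin_validation_error")
  n_bins <- floor(usable + 1e-9)
  v <- series[[var]]
  bin <- floor(series$t - series$t[1])
  f <- switch(stat,
              median = median,
              min = min,
              variance = function(z) mean((z - mean(z))^2),
              mean = mean)
  vals <- vapply(0:(n_bins - 1), function(k) {
    sel <- bin == k
    if (!any(sel)) return(NA_real_)
    f(v[sel])
  }, numeric(1))
  out <- tibble::tibble(bin_start = 0:(n_bins - 1), value = vals)
  attr(out, "feature_name") <- paste0(stat, "_", var)
  attr(out, "excluded_tail_s") <- tail_exclusion_s
  class(out) <- c("binned_series", class(tibble::tibble()))
  out
}

#' Zero out gross outliers by a robust deviation threshold
#'
#' Replaces with zero every value lying more than `threshold` robust
#' deviations from the series median, the pre-processing step used before
#' smoothing per-second feature trajectories. The deviation unit is the
#' median absolute deviation about the median (unscaled) by default; when
#' the MAD collapses to zero on non-constant data the rule stays literal, so
#' every value off the median is zeroed. Alternative units cover the other
#' readings of the threshold: `"mean_ad"` (mean absolute deviation about the
#' mean) and `"sd"`. Constant data are returned unchanged. Zeroed values are
#' kept as zeros downstream, not treated as missing.
#'
#' @param values Numeric vector, length >= 3.
#' @param threshold Number of deviations beyond which a value is zeroed
#'   (default 6).
#' @param unit `"mad"` (default), `"mean_ad"` or `"sd"`.
#' @return The vector with outliers zeroed; attribute `n_zeroed` counts the
#'   replacements.
#' @export
#' @examples
#' zero_outliers(c(1, 1, 1, 1, 100))
zero_outliers <- function(values, threshold = 6,
                          unit = c("mad", "mean_ad", "sd")) {
  unit <- match.arg(unit)
  if (length(values) < 3)
    abort("need at least 3 values", class = "rotakin_validation_error")
  if (all(values == values[1])) {
    attr(values, "n_zeroed") <- 0L
    return(values)
  }
  center <- if (unit == "mad") median(values) else mean(values)
  scale <- switch(unit,
                  mad = mad(values, constant = 1),
                  mean_ad = mean(abs(values - mean(values))),
                  sd = sd(values))
  out <- values
  bad <- abs(values - center) > threshold * scale
  out[bad] <- 0
  attr(out, "n_zeroed") <- sum(bad)
  out
}

#' Smooth a per-second binned series by local linear regression
#'
#' Locally weighted linear least squares with tricube weights (lowess with no
#' robustness iterations) over a sliding window of `span_bins` bins, the
#' smoothing applied to temporal trajectories of one-second features.
#' Windows truncate at the endpoints. Exact on linear input.
#'
#' @param binned A `binned_series`.
#' @param span_bins Odd window width in bins, default 5. Spans larger than
#'   the series are clipped with a warning.
#' @return A `binned_series` with smoothed `value`.
#' @export
smooth_binned <- function(binned, span_bins = 5) {
  n <- nrow(binned)
  if (span_bins > n) {
    warn(sprintf("span_bins %d exceeds the %d available bins; clipping",
                 span_bins, n))
    span_bins <- if (n %% 2 == 1) n else n - 1
  }
  if (span_bins < 2) return(binned)
  sm <- lowess(binned$bin_start, binned$value, f = span_bins / n, iter = 0)
  out <- binned
  out$value <- sm$y
  out
}
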
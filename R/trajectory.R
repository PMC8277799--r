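#' Construct a paw trajectory
#'
#' A paw trajectory is a tibble of calibrated paw-position samples for one
#' rotarod trial: time `t` in seconds from trial start, horizontal position
#' `x` and vertical position `y` in inches, with the trial identifier and
#' nominal sampling rate stored as attributes. The coordinate convention
#' follows the tracking calibration: origin at the lower-left of the rod
#' area, `y` increasing upward, `x` increasing rightward.
#'
#' @param t Numeric vector of sample times (seconds), strictly increasing,
#'   `t[1] >= 0`.
#' @param x,y Numeric vectors of horizontal / vertical paw position (inches).
#' @param trial_id Identifier for the trial.
#' @param rate_hz Nominal sampling rate in Hz (typically 15 or 30). When
#'   `NULL`, inferred from the median sampling interval.
#' @return A tibble of class `paw_trajectory` with columns `t`, `x`, `y` and
#'   attributes `trial_id` and `rate_hz`.
#' @export
#' @examples
#' tr <- paw_trajectory(t = (0:29) / 15, x = rep(1.5, 30), y = sin(0:29 / 5))
#' traj_rate(tr)
paw_trajectory <- function(t, x, y, trial_id = "trial", rate_hz = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (is.null(rate_hz)) {
    if (length(t) < 2) abort("need at least 2 samples to infer rate_hz",
                             class = "rotakin_validation_error")
    raw <- 1 / median(diff(t))
    rate_hz <- if (abs(raw - 15) / 15 <= 0.05) 15
               else if (abs(raw - 30) / 30 <= 0.05) 30
               else raw
  }
  out <- tibble::tibble(t = t, x = x, y = y)
  attr(out, "trial_id") <- trial_id
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("paw_trajectory", class(tibble::tibble()))
  validate_paw_trajectory(out)
}

#' Validate a paw trajectory's invariants
#'
#' Checks equal column lengths (>= 2), strictly increasing non-negative time,
#' finite coordinates, and that the median sampling interval is within 5% of
#' the nominal rate.
#'
#' @param traj A `paw_trajectory`.
#' @return `traj`, invisibly unchanged, or an error of class
#'   `rotakin_validation_error`.
#' @export
validate_paw_trajectory <- function(traj) {
  if (nrow(traj) < 2)
    abort("trajectory must have at least 2 samples",
          class = "rotakin_validation_error")
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y)) ||
      !all(is.finite(traj$t)))
    abort("trajectory contains non-finite values",
          class = "rotakin_validation_error")
  if (traj$t[1] < 0)
    abort("time must start at or after 0", class = "rotakin_validation_error")
  if (any(diff(traj$t) <= 0))
    abort("time must be strictly increasing",
          class = "rotakin_validation_error")
  rate <- traj_rate(traj)
  mdt <- median(diff(traj$t))
  if (abs(mdt - 1 / rate) > 0.05 / rate)
    abort(sprintf(
      "median sampling interval %.4f s is not within 5%% of 1/%g s",
      mdt, rate), class = "rotakin_validation_error")
  invisible(traj)
}

#' @rdname paw_trajectory
#' @param traj A `paw_trajectory`.
#' @export
traj_rate <- function(traj) attr(traj, "rate_hz")

#' @rdname paw_trajectory
#' @export
traj_id <- function(traj) attr(traj, "trial_id")

#' Trial duration in seconds
#' @param traj A `paw_trajectory`.
#' @return `max(t) - min(t)` in seconds.
#' @export
traj_duration <- function(traj) traj$t[nrow(traj)] - traj$t[1]

#' Calibration specification for raw tracking exports
#'
#' Tracking tools export either calibrated inches (when a pre-trial distance
#' calibration was applied) or raw pixels. When `pixels_per_inch` is given,
#' coordinates are divided by it on read.
#'
#' @param origin_description Free-text note of where the `[0, 0]` reference
#'   point sits (by convention the junction of the rod's lower border and the
#'   left partition).
#' @param unit Target unit; only `"inches"` is supported.
#' @param pixels_per_inch Optional positive scale when the raw export is in
#'   pixels.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(origin_description = "lower border of rod at left partition",
                             unit = "inches", pixels_per_inch = NULL) {
  if (!identical(unit, "inches"))
    abort("only inches are supported as the internal unit",
          class = "rotakin_validation_error")
  if (!is.null(pixels_per_inch) &&
      (!is.numeric(pixels_per_inch) || pixels_per_inch <= 0))
    abort("pixels_per_inch must be a positive number",
          class = "rotakin_validation_error")
  structure(list(origin_description = origin_description, unit = unit,
                 pixels_per_inch = pixels_per_inch),
            class = "calibration_spec")
}

#' Per-trial metadata record
#'
#' @param trial_id Trial identifier matching the trajectory.
#' @param mouse_id Mouse identifier.
#' @param trial_index Trial number within the series, 1, 2 or 3.
#' @param time_to_fall Rotarod score: seconds on the rod, > 0.
#' @param group Group label (e.g. control / treated / low-weight).
#' @param weight_g Body weight in grams, optional.
#' @return A one-row tibble of class `trial_record`.
#' @export
trial_record <- function(trial_id, mouse_id, trial_index, time_to_fall,
                         group = NA_character_, weight_g = NA_real_) {
  if (!trial_index %in% 1:3)
    abort("trial_index must be 1, 2 or 3", class = "rotakin_validation_error")
  if (!is.numeric(time_to_fall) || time_to_fall <= 0)
    abort("time_to_fall must be a positive number of seconds",
          class = "rotakin_validation_error")
  out <- tibble::tibble(trial_id = as.character(trial_id),
                        mouse_id = as.character(mouse_id),
                        trial_index = as.integer(trial_index),
                        time_to_fall = as.numeric(time_to_fall),
                        group = as.character(group),
                        weight_g = as.numeric(weight_g))
  class(out) <- c("trial_record", class(out))
  out
}

#' Check a trajectory against its trial record
#'
#' Tracking may run slightly past the fall; the trajectory must not extend
#' more than 1 s beyond the recorded time-to-fall.
#'
#' @param traj A `paw_trajectory`.
#' @param record The matching `trial_record`.
#' @return `TRUE` invisibly, or a validation error.
#' @export
check_trial_consistency <- function(traj, record) {
  if (traj$t[nrow(traj)] > record$time_to_fall[1] + 1)
    abort(sprintf("trajectory runs to %.2f s but time_to_fall is %.2f s",
                  traj$t[nrow(traj)], record$time_to_fall[1]),
          class = "rotakin_validation_error")
  invisible(TRUE)
}

# locate the data block in an export: returns list(skip, header, sep)
sniff_dialect <- function(lines) {
  score_sep <- function(s) sum(vapply(head(lines, 20), function(l)
    length(strsplit(l, s, fixed = TRUE)[[1]]) - 1L, integer(1)))
  sep <- if (score_sep("\t") > score_sep(",")) "\t" else ","
  is_numeric_row <- function(l) {
    tok <- trimws(strsplit(l, sep, fixed = TRUE)[[1]])
    tok <- tok[nzchar(tok)]
    num <- !is.na(suppressWarnings(as.numeric(tok))) |
      tolower(tok) %in% c("nan", "na")
    sum(num) >= 2 && sum(num) >= length(tok) - 1
  }
  first_data <- which(vapply(lines, is_numeric_row, logical(1)))[1]
  if (is.na(first_data))
    abort("no numeric data rows found", class = "rotakin_validation_error")
  header <- NULL
  if (first_data > 1) {
    cand <- trimws(strsplit(lines[first_data - 1], sep, fixed = TRUE)[[1]])
    if (length(cand) >= 2 && any(grepl("^[A-Za-z]", cand))) header <- cand
  }
  list(skip = first_data - 1L, header = header, sep = sep)
}

match_columns <- function(header, ncol) {
  if (!is.null(header)) {
    h <- tolower(trimws(header))
    ti <- which(grepl("^(t$|t[^a-z]|time)", h))[1]
    xi <- which(grepl("^x", h))[1]
    yi <- which(grepl("^y", h))[1]
    if (is.na(xi) || is.na(yi))
      abort("could not identify x and y columns from header",
            class = "rotakin_validation_error")
    return(list(t = if (is.na(ti)) NULL else ti, x = xi, y = yi))
  }
  if (ncol >= 3) list(t = 1L, x = 2L, y = 3L) else list(t = NULL, x = 1L, y = 2L)
}

#' Read a tracked paw-coordinate export
#'
#' Reads the columnar text files exported by video-tracking tools. Two
#' dialects are supported and auto-detected by header sniffing:
#' `"tracker"`-style files with preamble junk lines before the data block,
#' and `"generic-csv"` files with named `t`/`x`/`y` columns. The separator
#' (comma or tab) is sniffed. Rows with any non-numeric coordinate are
#' dropped with a message reporting the count. Coordinates are calibrated to
#' inches when the calibration carries a pixel scale.
#'
#' Time is taken from the file when a time column is present, otherwise
#' synthesized from `rate_hz`. Gaps longer than 3 nominal sampling intervals
#' are flagged with a warning, never interpolated.
#'
#' @param path Path to the export file.
#' @param dialect `"auto"` (default), `"tracker"` or `"generic-csv"`; the two
#'   named dialects are parsed identically after sniffing, the flag exists to
#'   force header interpretation.
#' @param calibration A [calibration_spec()].
#' @param trial_id Trial identifier to attach; defaults to the file name.
#' @param rate_hz Nominal sampling rate, required when the file has no time
#'   column.
#' @return A [paw_trajectory()].
#' @export
read_paw_trajectory <- function(path, dialect = c("auto", "tracker", "generic-csv"),
                                calibration = calibration_spec(),
                                trial_id = NULL, rate_hz = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort(sprintf("cannot read '%s': no such file", path),
          class = "rotakin_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  d <- sniff_dialect(lines)
  if (dialect == "generic-csv" && is.null(d$header))
    abort("generic-csv dialect requires a header row",
          class = "rotakin_validation_error")
  body <- lines[(d$skip + 1):length(lines)]
  toks <- lapply(body, function(l)
    suppressWarnings(as.numeric(trimws(strsplit(l, d$sep, fixed = TRUE)[[1]]))))
  ncols <- max(lengths(toks))
  mat <- do.call(rbind, lapply(toks, function(v) c(v, rep(NA, ncols - length(v)))))
  cols <- match_columns(d$header, ncol(mat))
  x <- mat[, cols$x]; y <- mat[, cols$y]
  t <- if (!is.null(cols$t)) mat[, cols$t] else NULL
  keep <- is.finite(x) & is.finite(y) & (is.null(t) | is.finite(t %||% x))
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("read_paw_trajectory: dropped %d row(s) with non-numeric coordinates",
                    dropped))
  x <- x[keep]; y <- y[keep]
  if (!is.null(t)) t <- t[keep]
  if (length(x) < 2)
    abort("fewer than 2 valid rows after cleaning",
          class = "rotakin_validation_error")
  if (is.null(t)) {
    if (is.null(rate_hz))
      abort("file has no time column; supply rate_hz",
            class = "rotakin_validation_error")
    t <- (seq_along(x) - 1) / rate_hz
  } else if (any(diff(t) <= 0)) {
    abort("time column is not strictly increasing after cleaning",
          class = "rotakin_validation_error")
  }
  if (!is.null(calibration$pixels_per_inch)) {
    x <- x / calibration$pixels_per_inch
    y <- y / calibration$pixels_per_inch
  }
  gap <- which(diff(t) > 3 * median(diff(t)))
  if (length(gap) > 0)
    warn(sprintf("trajectory has %d gap(s) longer than 3 sampling intervals (not interpolated)",
                 length(gap)))
  paw_trajectory(t, x, y,
                 trial_id = trial_id %||% sub("\\.[^.]*$", "", basename(path)),
                 rate_hz = rate_hz)
}

#' Write a paw trajectory as tidy CSV with a JSON metadata sidecar
#'
#' Values are serialized at full double precision so a write/read round trip
#' is bit-identical. The sidecar (same path with `.json` appended) records
#' trial id, rate and units.
#'
#' @param traj A `paw_trajectory`.
#' @param path Output CSV path.
#' @param sidecar Whether to write the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_paw_trajectory <- function(traj, path, sidecar = TRUE) {
  fmt <- function(v) sprintf("%.17g", v)
  df <- data.frame(trial_id = traj_id(traj), t = fmt(traj$t),
                   x = fmt(traj$x), y = fmt(traj$y))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(trial_id = traj_id(traj), rate_hz = traj_rate(traj),
                 unit = "inches", n_samples = nrow(traj))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Resample a trajectory onto a uniform time base
#'
#' Produces a uniform time base at `target_hz` spanning the original
#' duration. Downsampling is band-limited: a zero-phase FIR low-pass
#' (forward-backward filtering with reflective edge padding) removes content
#' above the new Nyquist frequency before cubic-spline evaluation on the new
#' grid. Resampling to the native rate of an already-uniform series is the
#' identity.
#'
#' @param traj A `paw_trajectory`.
#' @param target_hz Target rate in Hz, default 15 (the common analysis rate).
#' @return A `paw_trajectory` at `target_hz`.
#' @export
resample_trajectory <- function(traj, target_hz = 15) {
  if (target_hz <= 0)
    abort("target_hz must be positive", class = "rotakin_validation_error")
  rate <- traj_rate(traj)
  if (target_hz > 4 * rate)
    warn(sprintf("upsampling %g Hz data to %g Hz exceeds 4x the recorded content",
                 rate, target_hz))
  n <- nrow(traj)
  dts <- diff(traj$t)
  uniform <- max(abs(dts - 1 / rate)) < 1e-9 / rate + 1e-12
  if (uniform && abs(target_hz - rate) < 1e-12) return(traj)
  dur <- traj_duration(traj)
  m <- floor(dur * target_hz + 1e-9) + 1
  t_new <- traj$t[1] + (0:(m - 1)) / target_hz
  resample_axis <- function(v) {
    vf <- v
    if (target_hz < rate) {
      ord <- max(8L, min(64L, 2L * ((n - 1L) %/% 6L)))
      h <- signal::fir1(ord, target_hz / rate)
      pad <- min(3L * ord, n - 1L)
      vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
              2 * v[n] - rev(v[(n - pad):(n - 1)]))
      vf <- signal::filtfilt(filt = h, x = vp)[(pad + 1):(pad + n)]
    }
    stats::spline(traj$t, vf, xout = t_new, method = "fmm")$y
  }
  paw_trajectory(t_new, resample_axis(traj$x), resample_axis(traj$y),
                 trial_id = traj_id(traj), rate_hz = target_hz)
}
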
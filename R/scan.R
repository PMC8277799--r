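#' Spearman rank correlation with small-sample exact p
#'
#' Rank correlation with average-rank tie handling. The two-sided p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom; for `n <= exact_max` (default 9, the size of
#' the smallest subset analyses this scan supports) the exact permutation
#' p-value is computed by full enumeration of all `n!` rank permutations.
#'
#' @param xs,ys Numeric vectors of equal length >= 4.
#' @param exact_max Largest n at which the exact permutation p is used.
#' @return A one-row tibble: `rho`, `p`, `n`, `method`. All-tied input in
#'   either vector yields `rho = NA` with a warning (undefined, not silently
#'   zero).
#' @export
spearman_test <- function(xs, ys, exact_max = 9) {
  n <- length(xs)
  if (length(ys) != n || n < 4)
    abort("xs and ys must have equal length >= 4",
          class = "rotakin_validation_error")
  if (length(unique(xs)) == 1 || length(unique(ys)) == 1) {
    warn("all-tied input: Spearman correlation is undefined")
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          method = "degenerate"))
  }
  rho <- cor(xs, ys, method = "spearman")
  if (n <= exact_max) {
    rx <- rank(xs); ry <- rank(ys)
    perms <- permutations_of(n)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2)) *
      sqrt(sum((ry - mean(ry))^2))
    rho_perm <- as.vector((ry_perm - mean(ry)) %*% rx_c) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- max(2 * pt(-abs(tt), df = n - 2), .Machine$double.xmin)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n index matrix (n <= 9)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1] <- k
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Cumulative early-segment predictor scan
#'
#' For each cumulative initial segment of `T = 8, 9, 10, ...` seconds,
#' computes a named feature over the first `T` seconds of every eligible
#' trial and Spearman-correlates the values against the final time-to-fall.
#' The scan starts at 8 s, the first rod-speed increment. By the default
#' cohort rule (`"drop"`) a mouse leaves the scan once `T` exceeds its fall
#' time and the cohort size is non-increasing in `T`; with `"truncate"` the
#' scan stops at the shortest fall time so every `T` uses the full cohort.
#'
#' @param cohort Tibble with a `trajectory` list-column and a `time_to_fall`
#'   column (one row per mouse; filter to one trial per mouse first).
#' @param feature Catalog feature name, e.g. `"apen_pos"`.
#' @param axis `"vertical"` or `"horizontal"`.
#' @param t_start First segment end, default 8 s.
#' @param t_max Last segment end; default 30 s (the floor every mouse
#'   reaches).
#' @param cohort_rule `"drop"` or `"truncate"` (see above).
#' @param min_n Minimum cohort size; the curve truncates with a warning when
#'   eligibility falls below it (default 4).
#' @param ... Passed to [compute_features()] (e.g. `apen`, `sparc`).
#' @return A tibble of class `scan_curve`: `feature`, `axis`, `T`, `rho`,
#'   `p`, `n_mice`.
#' @export
scan_early_predictors <- function(cohort, feature, axis, t_start = 8,
                                  t_max = 30,
                                  cohort_rule = c("drop", "truncate"),
                                  min_n = 4, ...) {
  cohort_rule <- match.arg(cohort_rule)
  if (sum(cohort$time_to_fall >= t_start) < min_n)
    abort(sprintf("fewer than %d mice with time_to_fall >= %g s",
                  min_n, t_start), class = "rotakin_validation_error")
  if (cohort_rule == "truncate")
    t_max <- min(t_max, floor(min(cohort$time_to_fall)))
  T_values <- seq(t_start, t_max)
  rows <- list()
  for (T in T_values) {
    ok <- which(cohort$time_to_fall >= T)
    if (length(ok) < min_n) {
      warn(sprintf("scan truncated at T = %d s: cohort below %d mice", T, min_n))
      break
    }
    vals <- vapply(ok, function(i)
      first_t_feature(cohort$trajectory[[i]], axis, feature, T, ...),
      numeric(1))
    st <- spearman_test(vals, cohort$time_to_fall[ok])
    rows[[length(rows) + 1]] <-
      tibble::tibble(feature = feature, axis = axis, T = T,
                     rho = st$rho, p = st$p, n_mice = length(ok))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scan_curve", class(tibble::tibble()))
  out
}
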
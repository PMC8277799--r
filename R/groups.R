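#' Two-group comparison of a feature
#'
#' Two-tailed Student's t-test between two groups of per-trial feature
#' values, unpaired (e.g. low-weight vs high-weight, control vs treated) or
#' paired on matched mouse IDs (e.g. trial 1 vs trial 2 of the same mice).
#' Group summaries are reported as mean +/- SEM, the bar-chart convention.
#'
#' @param values_a,values_b Numeric vectors of feature values, n >= 2 each.
#' @param paired Paired test? Requires equal length and, when `ids_a`/`ids_b`
#'   are given, identical ID sets in the same order.
#' @param ids_a,ids_b Optional subject identifiers used to check pairing.
#' @param feature_name Label carried into the result.
#' @param var_equal Pool the variance (classic Student's t, default TRUE).
#' @return An object of class `group_comparison`; see [tidy.group_comparison()].
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE,
                           ids_a = NULL, ids_b = NULL,
                           feature_name = "feature", var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    abort("each group needs at least 2 values",
          class = "rotakin_validation_error")
  if (paired) {
    if (length(values_a) != length(values_b))
      abort("paired comparison requires equal group sizes",
            class = "rotakin_validation_error")
    if (!is.null(ids_a) && !identical(as.character(ids_a), as.character(ids_b)))
      abort("paired comparison requires matched IDs in the same order",
            class = "rotakin_validation_error")
  }
  ht <- t.test(values_a, values_b, paired = paired,
               var.equal = var_equal, alternative = "two.sided")
  sem <- function(v) sd(v) / sqrt(length(v))
  structure(list(
    feature_name = feature_name,
    paired = paired,
    group_a = list(mean = mean(values_a), sem = sem(values_a),
                   n = length(values_a)),
    group_b = list(mean = mean(values_b), sem = sem(values_b),
                   n = length(values_b)),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s %s comparison: %s\n",
              if (x$paired) "Paired" else "Unpaired", "two-group",
              x$feature_name))
  cat(sprintf("  group A: %.4g +/- %.4g (n = %d)\n",
              x$group_a$mean, x$group_a$sem, x$group_a$n))
  cat(sprintf("  group B: %.4g +/- %.4g (n = %d)\n",
              x$group_b$mean, x$group_b$sem, x$group_b$n))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with group means, SEMs, sizes, t, df and p.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(feature = x$feature_name, paired = x$paired,
                 mean_a = x$group_a$mean, sem_a = x$group_a$sem,
                 n_a = x$group_a$n,
                 mean_b = x$group_b$mean, sem_b = x$group_b$sem,
                 n_b = x$group_b$n,
                 statistic = x$statistic, df = x$df, p = x$p)
}

#' @export
glance.group_comparison <- function(x, ...)
  tibble::tibble(statistic = x$statistic, df = x$df, p = x$p)

#' PCA projection and MANOVA-Wilks group separation
#'
#' Standardizes the feature matrix column-wise (features differ in scale by
#' orders of magnitude), projects trials onto the first `n_pc` principal
#' components, and tests multivariate group-mean separation of the scores by
#' one-way MANOVA with Wilks' lambda and its F approximation.
#'
#' @param feature_matrix Numeric matrix or data frame, trials x features.
#' @param groups Group label per trial; >= 2 groups, each with n >= 3.
#' @param n_pc Number of leading components to keep, default 3.
#' @return An object of class `separation_result` with the PC `scores`
#'   tibble, `wilks_lambda`, `f`, degrees of freedom and `p`.
#' @export
pca_group_separation <- function(feature_matrix, groups, n_pc = 3) {
  x <- as.matrix(feature_matrix)
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    abort("need at least 2 groups", class = "rotakin_validation_error")
  if (any(table(groups) < 3))
    abort("each group needs at least 3 trials",
          class = "rotakin_validation_error")
  keep <- apply(x, 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d zero-variance feature column(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  sds <- apply(pc$x[, seq_len(n_pc), drop = FALSE], 2, sd)
  if (any(sds < 1e-10)) {
    warn("rank-deficient scores: reducing dimensionality")
    n_pc <- max(1, sum(sds >= 1e-10))
  }
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  fit <- manova(scores ~ groups)
  wl <- summary(fit, test = "Wilks")$stats
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(group = groups),
                              tibble::as_tibble(scores)),
    rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
    n_pc = n_pc,
    wilks_lambda = wl["groups", "Wilks"],
    f = wl["groups", "approx F"],
    df_num = wl["groups", "num Df"],
    df_den = wl["groups", "den Df"],
    p = wl["groups", "Pr(>F)"]
  ), class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("PCA + MANOVA-Wilks group separation on %d component(s)\n",
              x$n_pc))
  cat(sprintf("  Wilks' lambda = %.4g, F(%g, %g) = %.4g, p = %.4g\n",
              x$wilks_lambda, x$df_num, x$df_den, x$f, x$p))
  invisible(x)
}

#' Tidy a separation result
#'
#' @param x A `separation_result`.
#' @param ... Unused.
#' @return The per-trial PC score tibble with group labels.
#' @export
tidy.separation_result <- function(x, ...) x$scores

#' @export
glance.separation_result <- function(x, ...)
  tibble::tibble(wilks_lambda = x$wilks_lambda, f = x$f,
                 df_num = x$df_num, df_den = x$df_den, p = x$p,
                 n_pc = x$n_pc)
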
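#' Plot a paw trajectory
#'
#' Vertical and horizontal paw position against time, one panel per axis.
#'
#' @param object A [paw_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paw_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("x", "y"),
                            names_to = "axis", values_to = "position")
  df$axis <- ifelse(df$axis == "y", "vertical", "horizontal")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$position)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "paw position (in)",
                  title = traj_id(object)) +
    ggplot2::theme_minimal()
}

#' Plot an early-predictor scan curve
#'
#' p-value versus cumulative segment end, on a log scale with the 0.05
#' reference line, plus the Spearman rho track.
#'
#' @param object A `scan_curve` from [scan_early_predictors()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("rho", "p"),
                            names_to = "quantity", values_to = "value")
  ref <- tibble::tibble(quantity = "p", value = 0.05)
  ggplot2::ggplot(df, ggplot2::aes(.data$T, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$value),
                        linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "cumulative segment end T (s)",
                  title = sprintf("%s (%s) vs time-to-fall",
                                  object$feature[1], object$axis[1])) +
    ggplot2::theme_minimal()
}

#' Plot an early/late class dataset
#'
#' Scatter of the first two standardized feature columns coloured by class
#' (decision-boundary style view of the per-second bins).
#'
#' @param object A `class_dataset`.
#' @param features Optional pair of feature names to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.class_dataset <- function(object, features = NULL, ...) {
  feats <- features %||% head(attr(object, "feature_names"), 2)
  if (length(feats) == 1)
    return(ggplot2::ggplot(object,
                           ggplot2::aes(.data$bin_start, .data[[feats]],
                                        colour = .data$class)) +
             ggplot2::geom_point() + ggplot2::theme_minimal())
  ggplot2::ggplot(object, ggplot2::aes(.data[[feats[1]]], .data[[feats[2]]],
                                       colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = "early vs late per-second feature bins") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of a classifier report
#'
#' ROC built from the pooled out-of-fold decision values.
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_report <- function(object, ...) {
  roc <- pROC::roc(response = object$classes,
                   predictor = object$decision_values,
                   levels = c("early", "late"), direction = "auto",
                   quiet = TRUE)
  df <- tibble::tibble(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s kernel, AUC = %.3f, CV misclassification = %.3f",
                                  object$kernel, object$auc,
                                  object$cv_misclassification)) +
    ggplot2::theme_minimal()
}

#' Plot PCA group separation
#'
#' First two principal-component scores coloured by group.
#'
#' @param object A `separation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.separation_result <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("Wilks' lambda = %.3g, p = %.3g",
                                  object$wilks_lambda, object$p)) +
    ggplot2::theme_minimal()
}
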
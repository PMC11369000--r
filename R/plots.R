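# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot univariate results
#'
#' Per-analyte -log10 p values (unadjusted, BH, BY) with the significance
#' line at the chosen level, mirroring the familiar panel-test dot plot.
#'
#' @param object A `univariate_result`.
#' @param level Significance level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.univariate_result <- function(object, level = 0.05, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      c("p_unadjusted", "p_bh", "p_by"),
      names_to = "adjustment", values_to = "p"
    ) |>
    dplyr::mutate(
      adjustment = factor(.data$adjustment,
        levels = c("p_unadjusted", "p_bh", "p_by"),
        labels = c("unadjusted", "BH", "BY")
      ),
      label = analyte_labels()[.data$analyte]
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$label, -log10(.data$p), colour = .data$adjustment)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = -log10(level), linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = expression(-log[10](italic(p))),
      title = paste("Univariate tests,", object$sex, "stratum")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot of 1 - specificity against sensitivity.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores
#'
#' @param object A `pca_result`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot of subject scores colored by group, shaped by sex.
#' @export
autoplot.pca_result <- function(object, components = c(1, 2), ...) {
  stopifnot(length(components) == 2)
  vf <- object$variance_fraction
  cols <- paste0("PC", components)
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(
      .data[[cols[1]]], .data[[cols[2]]],
      colour = .data$group, shape = .data$sex
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cols[1], 100 * vf[components[1]]),
      y = sprintf("%s (%.1f%%)", cols[2], 100 * vf[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of a Jennrich test
#'
#' Histogram of the permuted statistics with the observed value marked.
#'
#' @param object A `jennrich_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jennrich_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$J)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$J_observed, colour = "red") +
    ggplot2::labs(
      x = "Permuted Jennrich statistic", y = "Count",
      title = sprintf(
        "Permutation null (J = %.2f, p = %.3f)",
        object$J_observed, object$p_permutation
      )
    ) +
    ggplot2::theme_minimal()
}
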
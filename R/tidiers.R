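# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy univariate results
#'
#' @param x A `univariate_result` from [run_univariate()].
#' @param ... Unused.
#' @return One row per analyte with the test used, statistic and
#'   unadjusted/BH/BY p values.
#' @export
tidy.univariate_result <- function(x, ...) {
  dplyr::select(x$tests, -"group_summaries")
}

#' @rdname tidy.univariate_result
#' @export
glance.univariate_result <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    n_analytes = nrow(x$tests),
    n_bh_significant = sum(x$tests$p_bh <= 0.05),
    n_by_significant = sum(x$tests$p_by <= 0.05),
    pairwise_family = x$pairwise_family
  )
}

#' Tidy a Spearman matrix into its edge list
#'
#' @param x A `spearman_matrix`.
#' @param ... Unused.
#' @export
tidy.spearman_matrix <- function(x, ...) correlation_edges(x)

#' Tidy a permutation Jennrich test
#'
#' `tidy()` returns the permuted statistics (one row per permutation);
#' `glance()` the one-row summary.
#'
#' @param x A `jennrich_test`.
#' @param ... Unused.
#' @export
tidy.jennrich_test <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$B), J = x$J_permuted)
}

#' @rdname tidy.jennrich_test
#' @export
glance.jennrich_test <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    groups_a = paste(x$groups$a, collapse = "+"),
    groups_b = paste(x$groups$b, collapse = "+"),
    include_aldosterone = x$include_aldosterone,
    n1 = x$n1, n2 = x$n2,
    J = x$J_observed, df = x$df, B = x$B,
    p_permutation = x$p_permutation,
    p_asymptotic = x$p_asymptotic,
    n_redraws = x$n_redraws
  )
}

#' Tidy a classifier evaluation
#'
#' `tidy()` returns the per-subject probabilities; `glance()` the one-row
#' evaluation summary.
#'
#' @param x A `classifier_evaluation` from [evaluate_classifier()].
#' @param ... Unused.
#' @export
tidy.classifier_evaluation <- function(x, ...) {
  attr(x, "probabilities")
}

#' @rdname tidy.classifier_evaluation
#' @export
glance.classifier_evaluation <- function(x, ...) {
  out <- x
  attr(out, "probabilities") <- NULL
  attr(out, "roc") <- NULL
  class(out) <- setdiff(class(out), "classifier_evaluation")
  out
}

#' Tidy PCA results
#'
#' `tidy()` returns subject scores; `glance()` per-component variance
#' fractions.
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @rdname tidy.pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_fraction),
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}
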
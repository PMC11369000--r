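# ROC construction and the closest-to-(0,1) optimal cutpoint.

#' ROC curve and AUC from class probabilities
#'
#' Builds the ROC curve (1 - specificity against sensitivity, thresholds at
#' every distinct probability) and the trapezoid AUC, which equals the
#' Mann-Whitney concordance probability with ties counted half. Curve and
#' AUC are computed with \pkg{pROC} (`direction = "<"`: cases are expected
#' to receive higher probabilities).
#'
#' @param probs Numeric vector of probabilities of being a case.
#' @param labels Case indicator: logical, 0/1, or a two-level factor whose
#'   second level is the case.
#' @return An object of class `roc_result`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' r$auc
roc_curve <- function(probs, labels) {
  y <- as_binary_class(labels)
  stopifnot(length(probs) == length(y), all(is.finite(probs)))
  if (length(unique(y)) < 2) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  r <- pROC::roc(
    response = y, predictor = probs, levels = c(0, 1), direction = "<",
    quiet = TRUE
  )
  pts <- tibble::tibble(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  ) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(
    list(
      points = pts, auc = as.numeric(pROC::auc(r)),
      n_cases = sum(y == 1), n_controls = sum(y == 0)
    ),
    class = "roc_result"
  )
}

#' Closest-to-(0,1) optimal cutpoint
#'
#' Selects the ROC point minimizing the Euclidean distance to perfect
#' classification, `sqrt((1 - Se)^2 + (1 - Sp)^2)`. Ties are broken by
#' higher sensitivity, then higher specificity.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `distance`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"), nrow(roc$points) >= 1)
  pts <- roc$points
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  cand <- which(d <= min(d) + 1e-12)
  cand <- cand[order(-pts$tpr[cand], pts$fpr[cand])]
  i <- cand[1]
  tibble::tibble(
    cutoff = pts$threshold[i],
    sensitivity = pts$tpr[i],
    specificity = 1 - pts$fpr[i],
    distance = d[i]
  )
}
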
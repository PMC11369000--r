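# Per-group Spearman correlation matrices and the strength-annotated edge
# list.

#' Spearman correlation matrix of one (sex, group) cell
#'
#' Mid-rank Spearman correlations on pairwise-complete observations, with
#' per-pair two-sided p values (asymptotic t approximation) and per-pair
#' complete-observation counts. Pairs with fewer than 4 complete
#' observations are flagged `NA` and unusable.
#'
#' @param cohort A cohort tibble.
#' @param sex,group Stratum and severity group.
#' @param include_aldosterone If `FALSE`, aldosterone (the analyte with
#'   missing values) is excluded, leaving an 8-analyte matrix.
#' @return An object of class `spearman_matrix`: list with `rho` (matrix),
#'   `p` (matrix), `n_effective` (matrix), `analytes`, `sex`, `group`,
#'   `n_subjects`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' sm <- spearman_matrix(cohort, "female", "HC")
#' round(sm$rho[1:3, 1:3], 2)
spearman_matrix <- function(cohort, sex, group, include_aldosterone = TRUE) {
  cohort <- validate_cohort_table(cohort)
  an <- steroid_analytes()
  if (!include_aldosterone) an <- setdiff(an, "aldosterone")
  sub <- cohort[cohort$sex == sex & cohort$group == group, an, drop = FALSE]
  if (nrow(sub) < 4) {
    stop(sprintf("group %s/%s has %d subjects; need >= 4", sex, group, nrow(sub)),
      call. = FALSE
    )
  }
  x <- as.matrix(sub)
  spearman_matrix_raw(x, sex = sex, group = group, n_subjects = nrow(sub))
}

# Core computation on a numeric matrix (columns = analytes); shared with the
# permutation test so permuted datasets skip tibble plumbing.
spearman_matrix_raw <- function(x, sex = NA, group = NA, n_subjects = nrow(x)) {
  an <- colnames(x)
  p_dim <- ncol(x)
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  obs <- !is.na(x)
  n_eff <- crossprod(obs * 1L)
  too_few <- n_eff < 4 & !diag(TRUE, p_dim)
  rho[too_few] <- NA_real_
  # two-sided p via the t approximation, t = r sqrt((n-2)/(1-r^2))
  tstat <- rho * sqrt(pmax(n_eff - 2, 0) / pmax(1 - rho^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(abs(tstat), df = pmax(n_eff - 2, 1), lower.tail = FALSE)
  pmat[abs(rho) >= 1] <- 0
  diag(pmat) <- NA_real_
  structure(
    list(
      rho = rho, p = pmat, n_effective = n_eff, analytes = an,
      sex = sex, group = group, n_subjects = n_subjects
    ),
    class = "spearman_matrix"
  )
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat(sprintf(
    "<spearman_matrix> %s/%s, n = %d, %d analytes\n",
    x$sex, x$group, x$n_subjects, length(x$analytes)
  ))
  print(round(x$rho, digits))
  invisible(x)
}

#' Strength-annotated correlation edge list
#'
#' Flattens a [spearman_matrix()] into one row per analyte pair with the
#' coefficient, its p value, the complete-pair count and the strength
#' taxonomy label (very high / high / moderate / low / little-or-none,
#' signed).
#'
#' @param sm A `spearman_matrix`.
#' @return A tibble with columns `analyte_i`, `analyte_j`, `rho`, `p`,
#'   `n_effective`, `category`, `sign`.
#' @export
correlation_edges <- function(sm) {
  stopifnot(inherits(sm, "spearman_matrix"))
  an <- sm$analytes
  idx <- which(upper.tri(sm$rho), arr.ind = TRUE)
  strength <- classify_strength(sm$rho[idx])
  tibble::tibble(
    analyte_i = an[idx[, 1]],
    analyte_j = an[idx[, 2]],
    rho = sm$rho[idx],
    p = sm$p[idx],
    n_effective = sm$n_effective[idx],
    category = strength$category,
    sign = strength$sign
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)))
}
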
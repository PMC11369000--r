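# Canonical 9-analyte plasma steroid panel, fixed column order used everywhere.

#' The canonical steroid panel
#'
#' Column names of the nine quantified plasma steroids, in the fixed order
#' used by every function in the package. `steroid_analytes()` returns the
#' machine-safe column names; `analyte_labels()` maps them to display names.
#'
#' @return A character vector of length 9.
#' @export
#' @examples
#' steroid_analytes()
steroid_analytes <- function() {
  c(
    "cortisone", "cortisol", "corticosterone", "deoxycortisol_11",
    "aldosterone", "androstenedione", "testosterone",
    "hydroxyprogesterone_17a", "progesterone"
  )
}

#' @rdname steroid_analytes
#' @export
analyte_labels <- function() {
  c(
    cortisone = "cortisone",
    cortisol = "cortisol",
    corticosterone = "corticosterone",
    deoxycortisol_11 = "11-deoxycortisol",
    aldosterone = "aldosterone",
    androstenedione = "androstenedione",
    testosterone = "testosterone",
    hydroxyprogesterone_17a = "17α-hydroxyprogesterone",
    progesterone = "progesterone"
  )
}

#' Allowed factor levels for cohort tables
#'
#' @return Character vectors of allowed `sex` and `group` labels.
#' @export
cohort_sexes <- function() c("female", "male")

#' @rdname cohort_sexes
#' @export
cohort_groups <- function() c("HC", "ME/CFSmm", "ME/CFSsa")

#' Classify correlation strength
#'
#' Bins a Spearman (or Pearson) coefficient into the conventional strength
#' taxonomy: very high (|r| in 0.9--1.0), high (0.7--0.9), moderate
#' (0.5--0.7), low (0.3--0.5) and little-or-none (< 0.3). Boundaries belong
#' to the upper bin (|r| = 0.9 is "very high"). The sign is reported
#' separately; r = 0 is labelled positive by convention.
#'
#' @param r Numeric vector of correlation coefficients in \[-1, 1\].
#' @return A tibble with columns `r`, `category` (ordered factor) and `sign`.
#' @export
#' @examples
#' classify_strength(c(0.89, -0.58, 0))
classify_strength <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlation coefficients must lie in [-1, 1]", call. = FALSE)
  }
  lev <- c("little-or-none", "low", "moderate", "high", "very high")
  category <- cut(pmin(abs(r), 1),
    breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
    labels = lev, right = FALSE
  )
  tibble::tibble(
    r = r,
    category = factor(as.character(category), levels = lev, ordered = TRUE),
    sign = ifelse(r < 0, "negative", "positive")
  )
}
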
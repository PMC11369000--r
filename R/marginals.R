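# Log-normal marginal specifications quantile-matched to median/IQR summaries.

#' Fit a log-normal marginal from a median and interquartile range
#'
#' Published cohort summaries report only the median and IQR per analyte.
#' A two-parameter log-normal is matched exactly to those three quantiles:
#' `mu_log = log(median)` and `sigma_log = log(q75/q25) / (2 * qnorm(0.75))`,
#' so the theoretical median and quartiles of the fitted distribution equal
#' the inputs. `q25 = median = q75` yields `sigma_log = 0`, a point mass.
#'
#' @param median,q25,q75 Positive concentrations (ng/mL) with
#'   `q25 <= median <= q75`.
#' @param analyte Optional analyte name used in error messages and output.
#' @return A one-row tibble with columns `analyte`, `median`, `q25`, `q75`,
#'   `mu_log`, `sigma_log`.
#' @export
#' @examples
#' fit_marginal(21.02, 17.25, 25.17, analyte = "cortisone")
fit_marginal <- function(median, q25, q75, analyte = NA_character_) {
  who <- if (is.na(analyte)) "marginal" else analyte
  if (!all(is.finite(c(median, q25, q75))) || any(c(median, q25, q75) <= 0)) {
    stop(sprintf("%s: median and quartiles must be finite and > 0", who),
      call. = FALSE
    )
  }
  if (!(q25 <= median && median <= q75)) {
    stop(sprintf("%s: quantiles must satisfy q25 <= median <= q75", who),
      call. = FALSE
    )
  }
  tibble::tibble(
    analyte = analyte,
    median = median, q25 = q25, q75 = q75,
    mu_log = log(median),
    sigma_log = log(q75 / q25) / (2 * stats::qnorm(0.75))
  )
}

#' Quantile function of a fitted marginal
#'
#' @param p Probabilities.
#' @param spec A one-row marginal spec from [fit_marginal()].
#' @return Concentrations in ng/mL.
#' @keywords internal
marginal_quantile <- function(p, spec) {
  exp(spec$mu_log + spec$sigma_log * stats::qnorm(p))
}

#' Reference marginal specifications for the study cohort
#'
#' Per-(sex, group, analyte) log-normal marginals fitted to the published
#' median/IQR summaries of the nine-steroid plasma panel in female and male
#' healthy controls (HC), mild/moderate (ME/CFSmm) and severely affected
#' (ME/CFSsa) ME/CFS patients. These parameterize the default synthetic
#' cohort.
#'
#' @return A tibble with one row per (sex, group, analyte) and the
#'   [fit_marginal()] columns.
#' @export
#' @examples
#' default_marginals()
default_marginals <- function() {
  # median, q25, q75 (ng/mL) in canonical panel order
  vals <- list(
    female = list(
      "HC" = list(
        c(21.02, 17.25, 25.17), c(94.55, 84.31, 138.70), c(1.23, 1.02, 1.87),
        c(0.12, 0.08, 0.25), c(0.10, 0.06, 0.16), c(0.78, 0.54, 1.11),
        c(0.23, 0.13, 0.30), c(0.23, 0.14, 0.37), c(0.09, 0.06, 0.15)
      ),
      "ME/CFSmm" = list(
        c(19.77, 15.62, 21.91), c(89.84, 68.87, 147.40), c(1.12, 0.85, 3.12),
        c(0.13, 0.09, 0.18), c(0.11, 0.08, 0.30), c(0.65, 0.43, 0.79),
        c(0.20, 0.15, 0.26), c(0.56, 0.20, 0.67), c(0.69, 0.19, 3.79)
      ),
      "ME/CFSsa" = list(
        c(19.57, 17.79, 23.00), c(110.70, 76.61, 131.40), c(1.97, 0.86, 4.06),
        c(0.22, 0.14, 0.56), c(0.08, 0.05, 0.13), c(0.80, 0.57, 1.14),
        c(0.23, 0.16, 0.32), c(1.24, 0.26, 1.66), c(0.36, 0.08, 1.10)
      )
    ),
    male = list(
      "HC" = list(
        c(20.67, 17.22, 25.17), c(120.80, 94.11, 134.30), c(1.89, 1.12, 3.43),
        c(0.16, 0.12, 0.26), c(0.07, 0.05, 0.16), c(0.74, 0.59, 0.86),
        c(4.78, 3.07, 6.75), c(0.64, 0.38, 0.83), c(0.07, 0.04, 0.08)
      ),
      "ME/CFSmm" = list(
        c(19.48, 15.29, 26.10), c(70.03, 55.18, 119.80), c(0.67, 0.47, 2.27),
        c(0.13, 0.08, 0.24), c(0.11, 0.05, 0.17), c(0.54, 0.42, 0.83),
        c(4.47, 2.81, 5.13), c(1.02, 0.65, 1.46), c(0.48, 0.12, 0.71)
      ),
      "ME/CFSsa" = list(
        c(20.24, 13.62, 25.01), c(99.32, 49.76, 153.50), c(1.47, 0.79, 10.37),
        c(0.23, 0.11, 0.84), c(0.07, 0.05, 0.21), c(0.65, 0.52, 0.96),
        c(3.32, 2.57, 4.89), c(0.55, 0.43, 1.14), c(0.07, 0.06, 0.23)
      )
    )
  )
  an <- steroid_analytes()
  purrr::map_dfr(names(vals), function(sx) {
    purrr::map_dfr(names(vals[[sx]]), function(gr) {
      rows <- purrr::imap_dfr(vals[[sx]][[gr]], function(v, i) {
        fit_marginal(v[1], v[2], v[3], analyte = an[i])
      })
      dplyr::mutate(rows, sex = sx, group = gr, .before = 1)
    })
  })
}

#' Reference group sizes for the study cohort
#'
#' @return A tibble with columns `sex`, `group`, `n` (female 12/20/24,
#'   male 17/8/6).
#' @export
default_group_sizes <- function() {
  tibble::tibble(
    sex = rep(cohort_sexes(), each = 3),
    group = rep(cohort_groups(), 2),
    n = c(12L, 20L, 24L, 17L, 8L, 6L)
  )
}
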
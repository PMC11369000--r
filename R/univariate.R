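# Per-analyte group comparisons with normality-gated test choice and FDR
# control (BH and BY).

#' Choose between one-way ANOVA and Kruskal-Wallis
#'
#' ANOVA is used only when every group passes a Shapiro-Wilk normality test
#' at alpha = 0.05; otherwise the Kruskal-Wallis rank test is used. This is
#' the standard normality gate for "ANOVA when normal, Kruskal-Wallis
#' otherwise" designs.
#'
#' @param samples A list of >= 2 numeric vectors (one per group), each with
#'   >= 3 non-missing values.
#' @param alpha Gate level (default 0.05).
#' @return `"anova"` or `"kruskal_wallis"`.
#' @export
choose_test <- function(samples, alpha = 0.05) {
  samples <- check_group_samples(samples)
  normal <- vapply(samples, function(x) {
    if (stats::sd(x) == 0) {
      return(FALSE) # constant group: not plausibly normal, and shapiro errors
    }
    stats::shapiro.test(x)$p.value >= alpha
  }, logical(1))
  if (all(normal)) "anova" else "kruskal_wallis"
}

check_group_samples <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples))) names(samples) <- paste0("group", seq_along(samples))
  samples <- purrr::map(samples, function(x) x[!is.na(x)])
  small <- names(samples)[vapply(samples, length, integer(1)) < 3]
  if (length(small)) {
    stop("groups with fewer than 3 non-missing values: ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  samples
}

#' Kruskal-Wallis and one-way ANOVA on a list of group samples
#'
#' Thin wrappers around [stats::kruskal.test()] (mid-ranks, tie-corrected H,
#' chi-square approximation) and [stats::oneway.test()] with
#' `var.equal = TRUE` (the classic between/within mean-square F). When every
#' value across all groups is identical the Kruskal-Wallis tie-correction
#' denominator vanishes; by convention `H = 0`, `p = 1` is returned with a
#' warning.
#'
#' @inheritParams choose_test
#' @return A one-row tibble with `statistic`, `df` (`df1`/`df2` for ANOVA)
#'   and `p_value`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
kruskal_wallis <- function(samples) {
  samples <- check_group_samples(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)))
  if (length(unique(x)) == 1) {
    warning("all values identical across groups; returning H = 0, p = 1")
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' @rdname kruskal_wallis
#' @export
anova_oneway <- function(samples) {
  samples <- check_group_samples(samples)
  if (all(vapply(samples, stats::sd, numeric(1)) == 0)) {
    stop("zero within-group variance in every group; ANOVA undefined",
      call. = FALSE
    )
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)))
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ft$statistic),
    df1 = unname(ft$parameter[1]),
    df2 = unname(ft$parameter[2]),
    p_value = ft$p.value
  )
}

#' Benjamini-Hochberg and Benjamini-Yekutieli step-up adjustment
#'
#' Step-up FDR adjustment of a p-value vector, returned in input order.
#' BH: `adj(i) = min over j >= i of min(1, m p(j) / j)` on the ascending
#' sort; BY multiplies each term by the harmonic factor
#' `c(m) = sum_{k<=m} 1/k`, valid under arbitrary dependence. Both delegate
#' to [stats::p.adjust()].
#'
#' @param p Numeric vector of p values in (0, 1].
#' @return Adjusted p values, same length and order as the input.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.04, 0.03, 0.002))
adjust_bh <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_by <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BY")
}

check_pvalues <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

group_pairs <- function() {
  list(
    c("HC", "ME/CFSmm"),
    c("HC", "ME/CFSsa"),
    c("ME/CFSmm", "ME/CFSsa")
  )
}

# Two-sided Mann-Whitney on mid-ranks: exact null enumeration when both
# groups are small (<= 8) and tie-free, otherwise the tie-corrected normal
# approximation with continuity correction.
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  exact <- max(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pairwise two-group comparison for one analyte
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two severity
#' groups within a sex stratum. Family-wise BH adjustment across pairs is
#' applied by [run_univariate()]; this returns the unadjusted result.
#'
#' @param cohort A cohort tibble.
#' @param analyte One panel analyte name.
#' @param sex `"female"` or `"male"`.
#' @param pair Character vector of two group labels.
#' @return A one-row tibble: `analyte`, `sex`, `pair`, `statistic`,
#'   `p_unadjusted`.
#' @export
pairwise_two_group <- function(cohort, analyte, sex, pair) {
  cohort <- validate_cohort_table(cohort)
  stopifnot(analyte %in% steroid_analytes(), length(pair) == 2)
  vals <- purrr::map(pair, function(g) {
    v <- cohort[[analyte]][cohort$sex == sex & cohort$group == g]
    v[!is.na(v)]
  })
  names(vals) <- pair
  check_group_samples(vals)
  mw <- mann_whitney(vals[[1]], vals[[2]])
  tibble::tibble(
    analyte = analyte, sex = sex,
    pair = paste(pair, collapse = " vs "),
    statistic = mw$statistic, p_unadjusted = mw$p_value
  )
}

#' Univariate analysis of a sex stratum
#'
#' For each of the nine analytes: drops missing values, gates between
#' one-way ANOVA and Kruskal-Wallis by per-group Shapiro-Wilk normality,
#' computes the three-group test, and BH/BY-adjusts the nine p values within
#' the stratum. Also runs all 3 pairwise Mann-Whitney comparisons per
#' analyte, BH-adjusted across the pairwise family (default 9 analytes x 3
#' pairs = 27 tests; set `pairwise_family = "per_pair"` to adjust across the
#' 9 analytes within each pair instead).
#'
#' @param cohort A cohort tibble.
#' @param sex Stratum to analyze.
#' @param alpha Normality-gate level (default 0.05).
#' @param pairwise_family `"per_stratum"` (27-test family, default) or
#'   `"per_pair"` (9-test families).
#' @return An object of class `univariate_result`: a list with tibbles
#'   `tests` (one row per analyte: `test_used`, `statistic`,
#'   `p_unadjusted`, `p_bh`, `p_by`, per-group n/median/IQR) and `pairwise`
#'   (27 rows: `p_unadjusted`, `p_bh`).
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' res <- run_univariate(cohort, "female")
#' res$tests
run_univariate <- function(cohort, sex, alpha = 0.05,
                           pairwise_family = c("per_stratum", "per_pair")) {
  cohort <- validate_cohort_table(cohort)
  pairwise_family <- match.arg(pairwise_family)
  stopifnot(sex %in% cohort_sexes())
  stratum <- dplyr::filter(cohort, .data$sex == .env$sex)
  if (nrow(stratum) == 0) stop("no subjects in stratum '", sex, "'", call. = FALSE)

  tests <- purrr::map_dfr(steroid_analytes(), function(a) {
    samples <- purrr::map(cohort_groups(), function(g) {
      v <- stratum[[a]][stratum$group == g]
      v[!is.na(v)]
    })
    names(samples) <- cohort_groups()
    test_used <- tryCatch(choose_test(samples, alpha = alpha),
      error = function(e) stop("analyte ", a, ": ", conditionMessage(e), call. = FALSE)
    )
    res <- if (test_used == "anova") {
      r <- anova_oneway(samples)
      tibble::tibble(statistic = r$statistic, p_value = r$p_value)
    } else {
      r <- kruskal_wallis(samples)
      tibble::tibble(statistic = r$statistic, p_value = r$p_value)
    }
    summaries <- purrr::imap_dfr(samples, function(v, g) {
      tibble::tibble(
        group = g, n = length(v), median = stats::median(v),
        q25 = unname(stats::quantile(v, 0.25)),
        q75 = unname(stats::quantile(v, 0.75))
      )
    })
    tibble::tibble(
      analyte = a, sex = sex, test_used = test_used,
      statistic = res$statistic, p_unadjusted = res$p_value,
      group_summaries = list(summaries)
    )
  })
  tests$p_bh <- adjust_bh(tests$p_unadjusted)
  tests$p_by <- adjust_by(tests$p_unadjusted)
  tests <- dplyr::relocate(tests, "group_summaries", .after = "p_by")

  pairwise <- purrr::map_dfr(steroid_analytes(), function(a) {
    purrr::map_dfr(group_pairs(), function(pr) {
      pairwise_two_group(stratum, a, sex, pr)
    })
  })
  if (pairwise_family == "per_stratum") {
    pairwise$p_bh <- adjust_bh(pairwise$p_unadjusted)
  } else {
    pairwise <- pairwise |>
      dplyr::group_by(.data$pair) |>
      dplyr::mutate(p_bh = adjust_bh(.data$p_unadjusted)) |>
      dplyr::ungroup()
  }

  structure(
    list(tests = tests, pairwise = pairwise, sex = sex,
         pairwise_family = pairwise_family),
    class = "univariate_result"
  )
}

#' @export
print.univariate_result <- function(x, ...) {
  cat("<univariate_result> stratum:", x$sex, "\n")
  print(dplyr::select(x$tests, -"group_summaries"))
  invisible(x)
}
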
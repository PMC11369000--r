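# Synthetic-cohort configuration: group sizes, marginals, dependence targets,
# missingness and seeding.

#' Reference Spearman dependence targets
#'
#' 9x9 target Spearman matrices per (sex, group), populated with the
#' significant per-group coefficients reported for the study cohort;
#' unreported pairs default to 0. Matrices are symmetric with unit diagonal
#' and are PSD-repaired on the latent (copula) scale at simulation time.
#'
#' @return A named list of 9x9 matrices keyed `"<sex>.<group>"`.
#' @export
default_spearman_targets <- function() {
  an <- steroid_analytes()
  pairs <- list(
    female.HC = list(
      c("cortisol", "corticosterone", 0.89),
      c("androstenedione", "hydroxyprogesterone_17a", 0.79),
      c("testosterone", "androstenedione", 0.78),
      c("testosterone", "hydroxyprogesterone_17a", 0.78),
      c("cortisol", "cortisone", 0.69),
      c("androstenedione", "cortisone", 0.66),
      c("testosterone", "corticosterone", 0.62),
      c("progesterone", "hydroxyprogesterone_17a", 0.62)
    ),
    `female.ME/CFSmm` = list(
      c("cortisol", "corticosterone", 0.83),
      c("cortisol", "cortisone", 0.78),
      c("progesterone", "hydroxyprogesterone_17a", 0.77),
      c("testosterone", "androstenedione", 0.67),
      c("androstenedione", "cortisone", 0.47),
      c("corticosterone", "deoxycortisol_11", 0.69),
      c("corticosterone", "cortisone", 0.54),
      c("cortisol", "deoxycortisol_11", 0.52),
      c("hydroxyprogesterone_17a", "aldosterone", -0.58)
    ),
    `female.ME/CFSsa` = list(
      c("cortisol", "corticosterone", 0.84),
      c("progesterone", "hydroxyprogesterone_17a", 0.83),
      c("cortisol", "deoxycortisol_11", 0.84),
      c("corticosterone", "deoxycortisol_11", 0.67)
    ),
    male.HC = list(
      c("progesterone", "hydroxyprogesterone_17a", 0.81),
      c("cortisol", "corticosterone", 0.79),
      c("testosterone", "progesterone", 0.79),
      c("testosterone", "hydroxyprogesterone_17a", 0.71),
      c("corticosterone", "deoxycortisol_11", 0.60),
      c("androstenedione", "hydroxyprogesterone_17a", 0.57)
    ),
    `male.ME/CFSmm` = list(
      c("cortisol", "corticosterone", 0.83),
      c("cortisol", "deoxycortisol_11", 0.88),
      c("androstenedione", "cortisol", 0.88),
      c("corticosterone", "cortisone", 0.81),
      c("androstenedione", "deoxycortisol_11", 0.81),
      c("androstenedione", "cortisone", 0.79),
      c("androstenedione", "corticosterone", 0.76)
    ),
    `male.ME/CFSsa` = list(
      c("corticosterone", "deoxycortisol_11", 0.89),
      c("androstenedione", "corticosterone", 0.94),
      c("androstenedione", "deoxycortisol_11", 0.94),
      c("progesterone", "cortisol", 0.94)
    )
  )
  purrr::map(pairs, function(ps) {
    m <- diag(9)
    dimnames(m) <- list(an, an)
    for (p in ps) {
      r <- as.numeric(p[3])
      m[p[1], p[2]] <- r
      m[p[2], p[1]] <- r
    }
    m
  })
}

#' Build a synthetic-cohort configuration
#'
#' Bundles everything [simulate_cohort()] needs: per-(sex, group) sizes,
#' log-normal marginal specs, target Spearman matrices, per-analyte MCAR
#' missingness rates and a seed. `default_cohort_config()` encodes the
#' study conditions: group sizes female 12/20/24 and male 17/8/6, marginals
#' quantile-matched to the published median/IQR table, the published
#' significant Spearman coefficients as dependence targets, and a 0.2
#' missingness rate for aldosterone (the one analyte with missing data).
#'
#' @param group_sizes Tibble with columns `sex`, `group`, `n`.
#' @param marginals Tibble as returned by [default_marginals()].
#' @param spearman_targets Named list of 9x9 matrices keyed `"<sex>.<group>"`.
#' @param missing_rates Named numeric vector of per-analyte MCAR rates.
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @export
#' @examples
#' cfg <- default_cohort_config(seed = 1)
#' cohort <- simulate_cohort(cfg)
cohort_config <- function(group_sizes, marginals, spearman_targets,
                          missing_rates = c(aldosterone = 0.2), seed = 1L) {
  an <- steroid_analytes()
  stopifnot(
    all(c("sex", "group", "n") %in% names(group_sizes)),
    all(group_sizes$n >= 1),
    all(group_sizes$sex %in% cohort_sexes()),
    all(group_sizes$group %in% cohort_groups())
  )
  if (length(missing_rates)) {
    if (!all(names(missing_rates) %in% an)) {
      stop("missing_rates names must be panel analytes", call. = FALSE)
    }
    stopifnot(all(missing_rates >= 0 & missing_rates <= 1))
  }
  keys <- paste(group_sizes$sex, group_sizes$group, sep = ".")
  for (k in keys) {
    m <- spearman_targets[[k]]
    if (is.null(m)) stop(sprintf("no spearman target for block '%s'", k), call. = FALSE)
    stopifnot(identical(dim(m), c(9L, 9L)))
    if (max(abs(m - t(m))) > 1e-10 || any(abs(diag(m) - 1) > 1e-10)) {
      stop(sprintf("spearman target '%s' must be symmetric with unit diagonal", k),
        call. = FALSE
      )
    }
    if (any(abs(m) > 1)) {
      stop(sprintf("spearman target '%s' has entries outside [-1, 1]", k),
        call. = FALSE
      )
    }
  }
  missing <- dplyr::anti_join(group_sizes, marginals, by = c("sex", "group"))
  if (nrow(missing) > 0) {
    stop("marginals missing for some (sex, group) blocks", call. = FALSE)
  }
  structure(
    list(
      group_sizes = group_sizes, marginals = marginals,
      spearman_targets = spearman_targets, missing_rates = missing_rates,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_cohort_config <- function(seed = 1L,
                                  missing_rates = c(aldosterone = 0.2)) {
  cohort_config(
    group_sizes = default_group_sizes(),
    marginals = default_marginals(),
    spearman_targets = default_spearman_targets(),
    missing_rates = missing_rates,
    seed = seed
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  blocks:", nrow(x$group_sizes), " total n:", sum(x$group_sizes$n), "\n")
  cat(
    "  missing rates:",
    if (length(x$missing_rates)) {
      paste(names(x$missing_rates), x$missing_rates, sep = "=", collapse = ", ")
    } else "none", "\n"
  )
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
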
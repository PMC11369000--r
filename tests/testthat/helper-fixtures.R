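# Shared fixtures built in code.

# A small single-block config with no missing data, handy for fast tests.
tiny_config <- function(n = 30L, sex = "female", group = "HC", seed = 1L,
                        missing_rates = stats::setNames(numeric(0), character(0))) {
  cohort_config(
    group_sizes = tibble::tibble(sex = sex, group = group, n = n),
    marginals = default_marginals(),
    spearman_targets = default_spearman_targets(),
    missing_rates = missing_rates,
    seed = seed
  )
}

# A feasible (PSD on the copula scale) 9x9 Spearman target: exchangeable
# correlation rho within a leading block, zero elsewhere.
block_target <- function(rho = 0.8, block = 1:4) {
  an <- steroid_analytes()
  m <- diag(9)
  dimnames(m) <- list(an, an)
  m[block, block] <- rho
  diag(m) <- 1
  m
}

# Cohort with two same-sex groups drawn from a shared dependence structure,
# used for permutation-null and classifier-null experiments.
two_group_cohort <- function(n1, n2, target1 = block_target(0.5),
                             target2 = target1, seed = 1L,
                             groups = c("ME/CFSmm", "ME/CFSsa")) {
  tg <- default_spearman_targets()
  tg[[paste0("female.", groups[1])]] <- target1
  tg[[paste0("female.", groups[2])]] <- target2
  cfg <- cohort_config(
    group_sizes = tibble::tibble(
      sex = "female", group = groups, n = c(n1, n2)
    ),
    marginals = default_marginals(),
    spearman_targets = tg,
    missing_rates = stats::setNames(numeric(0), character(0)),
    seed = seed
  )
  simulate_cohort(cfg)
}

# Manual ROC point set for cutoff tests.
manual_roc <- function(fpr, tpr, threshold = seq_along(fpr)) {
  structure(
    list(
      points = tibble::tibble(threshold = threshold, fpr = fpr, tpr = tpr),
      auc = NA_real_, n_cases = NA_integer_, n_controls = NA_integer_
    ),
    class = "roc_result"
  )
}

# Brute-force concordance AUC: share of case/control pairs ranked correctly,
# ties counted half.
auc_by_counting <- function(probs, y) {
  cases <- probs[y == 1]
  controls <- probs[y == 0]
  cmp <- outer(cases, controls, ">") + 0.5 * outer(cases, controls, "==")
  mean(cmp)
}
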
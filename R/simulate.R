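# Gaussian-copula cohort simulation with log-normal marginals.

# Deterministic substream seed per (sex, group) block: a polynomial hash of
# the block key folded with the user seed, so adding or reordering blocks
# never perturbs the draws of the others.
block_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483647)
}

#' Simulate a synthetic steroid-panel cohort
#'
#' Draws each (sex, group) block from a Gaussian copula whose latent Pearson
#' correlation is the elementwise `2 sin(pi rho/6)` transform of the block's
#' target Spearman matrix (PSD-repaired by eigenvalue clipping), maps each
#' latent coordinate through its quantile-matched log-normal marginal, then
#' masks analytes missing completely at random at the configured per-analyte
#' rates. Deterministic given `config$seed`; each block uses an independent
#' substream derived from the seed and the block key.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble: `subject_id`, `sex`, `group`, then the nine
#'   analyte columns (ng/mL, `NA` = missing) in canonical order.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 42))
#' dplyr::count(cohort, sex, group)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  an <- steroid_analytes()
  blocks <- config$group_sizes
  out <- purrr::pmap_dfr(blocks, function(sex, group, n) {
    key <- paste(sex, group, sep = ".")
    spec <- dplyr::filter(config$marginals, .data$sex == .env$sex, .data$group == .env$group)
    spec <- spec[match(an, spec$analyte), ]
    if (anyNA(spec$analyte)) {
      stop(sprintf("block '%s': marginals must cover all 9 analytes", key),
        call. = FALSE
      )
    }
    target <- config$spearman_targets[[key]][an, an]
    latent_corr <- nearest_psd(spearman_to_copula(target))
    diag(latent_corr) <- 1
    ev_min <- min(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      stop(sprintf(
        "block '%s': copula matrix not repairable to PSD (min eigenvalue %.3g)",
        key, ev_min
      ), call. = FALSE)
    }
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(block_seed(config$seed, key))
    z <- matrix(stats::rnorm(n * 9), nrow = n) %*% chol(latent_corr)
    conc <- exp(
      matrix(spec$mu_log, n, 9, byrow = TRUE) +
        matrix(spec$sigma_log, n, 9, byrow = TRUE) * z
    )
    colnames(conc) <- an
    for (a in names(config$missing_rates)) {
      rate <- config$missing_rates[[a]]
      if (rate > 0) conc[stats::runif(n) < rate, a] <- NA_real_
    }
    tibble::tibble(
      subject_id = sprintf(
        "%s_%s_%03d", toupper(substr(sex, 1, 1)),
        gsub("[^A-Za-z]", "", group), seq_len(n)
      ),
      sex = sex, group = group
    ) |>
      dplyr::bind_cols(tibble::as_tibble(conc))
  })
  out
}

# Save/restore the global RNG state so simulation functions do not disturb
# the caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
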
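# Jennrich's chi-square statistic for equality of two correlation matrices,
# and its permutation wrapper for Spearman matrices.

#' Jennrich statistic for equality of two correlation matrices
#'
#' With pooled correlation `Rbar = (n1 R1 + n2 R2) / (n1 + n2)` and
#' `c = n1 n2 / (n1 + n2)`, let `Z = sqrt(c) Rbar^{-1} (R1 - R2)` and `S`
#' have entries `delta_ij + rbar_ij * rbar^ij` (`rbar^ij` the entries of
#' `Rbar^{-1}`). The statistic is
#' `J = tr(Z^2) / 2 - diag(Z)' S^{-1} diag(Z)`, asymptotically chi-square
#' with `p (p - 1) / 2` degrees of freedom under equality (for Pearson
#' matrices from multivariate normal samples). A near-singular pooled matrix
#' is ridged by `ridge` on the diagonal before inversion.
#'
#' @param R1,R2 Symmetric unit-diagonal correlation matrices, same dimension.
#' @param n1,n2 Group sample sizes.
#' @param ridge Diagonal ridge applied when the pooled matrix is
#'   numerically singular (default 1e-8).
#' @return A list with `J`, `df`.
#' @export
#' @examples
#' R <- diag(4)
#' jennrich_statistic(R, R, 50, 50)$J # 0
jennrich_statistic <- function(R1, R2, n1, n2, ridge = 1e-8) {
  stopifnot(
    is.matrix(R1), is.matrix(R2), identical(dim(R1), dim(R2)),
    nrow(R1) == ncol(R1), nrow(R1) >= 2, n1 > 0, n2 > 0
  )
  if (anyNA(R1) || anyNA(R2)) {
    stop("correlation matrices contain unusable (NA) entries", call. = FALSE)
  }
  p <- nrow(R1)
  cc <- n1 * n2 / (n1 + n2)
  Rbar <- (n1 * R1 + n2 * R2) / (n1 + n2)
  Rinv <- tryCatch(solve(Rbar), error = function(e) NULL)
  if (is.null(Rinv)) {
    Rinv <- tryCatch(solve(Rbar + diag(ridge, p)), error = function(e) NULL)
    if (is.null(Rinv)) {
      ev <- min(eigen(Rbar, symmetric = TRUE, only.values = TRUE)$values)
      stop(sprintf(
        "pooled correlation matrix singular (min eigenvalue %.3g); increase ridge",
        ev
      ), call. = FALSE)
    }
  }
  Z <- sqrt(cc) * Rinv %*% (R1 - R2)
  S <- diag(p) + Rbar * Rinv
  dz <- diag(Z)
  J <- 0.5 * sum(Z * t(Z)) - drop(crossprod(dz, solve(S, dz)))
  list(J = max(J, 0), df = p * (p - 1) / 2)
}

#' Permutation Jennrich test between two subject groups
#'
#' Compares the Spearman correlation matrices of two groups of subjects
#' within a sex stratum. The observed statistic is the Jennrich J of the
#' two mid-rank Spearman matrices (pairwise-complete observations, scalar n
#' = group subject count). The permutation null shuffles subjects between
#' the two groups keeping group sizes fixed, recomputes both matrices and J
#' for each of `B` permutations, and reports the upper-tail estimate
#' `p = (1 + #\{J_perm >= J_obs\}) / (B + 1)`. Permutations whose pooled
#' matrix is singular even after ridging are redrawn (more than 10% redraws
#' aborts). The asymptotic chi-square p value is reported alongside as a
#' diagnostic only; the chi-square null is derived for Pearson matrices and
#' the permutation null is the valid reference for Spearman input.
#'
#' @param cohort A cohort tibble.
#' @param sex Stratum.
#' @param groups_a,groups_b Character vectors of severity groups forming the
#'   two sides (e.g. `"HC"` vs `c("ME/CFSmm", "ME/CFSsa")`).
#' @param include_aldosterone If `FALSE`, drop aldosterone (df 36 -> 28).
#' @param B Number of permutations (>= 99; default 1000).
#' @param seed Integer seed; the test is deterministic given it.
#' @param ridge Ridge for near-singular pooled matrices.
#' @return An object of class `jennrich_test`: list with `J_observed`,
#'   `df`, `B`, `J_permuted`, `p_permutation`, `p_asymptotic`, `n1`, `n2`,
#'   `groups`, `include_aldosterone`, `n_redraws`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' jt <- jennrich_test(cohort, "female", "HC", c("ME/CFSmm", "ME/CFSsa"),
#'   B = 199, seed = 1
#' )
#' jt$p_permutation
jennrich_test <- function(cohort, sex, groups_a, groups_b,
                          include_aldosterone = TRUE, B = 1000, seed = 1L,
                          ridge = 1e-8) {
  cohort <- validate_cohort_table(cohort)
  stopifnot(B >= 99, length(intersect(groups_a, groups_b)) == 0)
  an <- steroid_analytes()
  if (!include_aldosterone) an <- setdiff(an, "aldosterone")
  stratum <- cohort[cohort$sex == sex, , drop = FALSE]
  xa <- as.matrix(stratum[stratum$group %in% groups_a, an, drop = FALSE])
  xb <- as.matrix(stratum[stratum$group %in% groups_b, an, drop = FALSE])
  n1 <- nrow(xa)
  n2 <- nrow(xb)
  if (n1 < 4 || n2 < 4) {
    stop("both sides need >= 4 subjects for a Spearman matrix", call. = FALSE)
  }

  stat_for <- function(x1, x2) {
    r1 <- spearman_matrix_raw(x1)$rho
    r2 <- spearman_matrix_raw(x2)$rho
    jennrich_statistic(r1, r2, nrow(x1), nrow(x2), ridge = ridge)
  }
  obs <- stat_for(xa, xb)

  pooled <- rbind(xa, xb)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  j_perm <- numeric(B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n1 + n2, n1)
      jb <- tryCatch(
        stat_for(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])$J,
        error = function(e) NA_real_
      )
      if (!is.na(jb)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 0.1 * B) {
        stop("more than 10% of permutations yielded singular/unusable matrices",
          call. = FALSE
        )
      }
    }
    j_perm[b] <- jb
  }

  structure(
    list(
      J_observed = obs$J, df = obs$df, B = B, J_permuted = j_perm,
      p_permutation = (1 + sum(j_perm >= obs$J)) / (B + 1),
      p_asymptotic = stats::pchisq(obs$J, obs$df, lower.tail = FALSE),
      n1 = n1, n2 = n2, sex = sex,
      groups = list(a = groups_a, b = groups_b),
      include_aldosterone = include_aldosterone, n_redraws = n_redraws,
      seed = as.integer(seed)
    ),
    class = "jennrich_test"
  )
}

#' @export
print.jennrich_test <- function(x, ...) {
  cat(sprintf(
    "<jennrich_test> %s: {%s} (n=%d) vs {%s} (n=%d)%s\n",
    x$sex, paste(x$groups$a, collapse = ","), x$n1,
    paste(x$groups$b, collapse = ","), x$n2,
    if (x$include_aldosterone) "" else " [aldosterone excluded]"
  ))
  cat(sprintf(
    "  J = %.3f (df = %d), permutation p = %.4g (B = %d), asymptotic p = %.4g\n",
    x$J_observed, x$df, x$p_permutation, x$B, x$p_asymptotic
  ))
  invisible(x)
}
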
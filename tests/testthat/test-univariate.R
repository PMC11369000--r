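# Univariate machinery: test gating, rank tests, FDR adjustment, pairwise
# comparisons and the stratum-level driver.

test_that("normality gate picks ANOVA for normal groups, KW for heavy tails", {
  set.seed(21)
  anova_picks <- replicate(40, {
    s <- replicate(3, rnorm(50, 10, 2), simplify = FALSE)
    choose_test(s) == "anova"
  })
  expect_gte(mean(anova_picks), 0.85)

  set.seed(22)
  kw_picks <- replicate(40, {
    s <- list(rnorm(50), rnorm(50), exp(rnorm(50, sd = 1.5)))
    choose_test(s) == "kruskal_wallis"
  })
  expect_gte(mean(kw_picks), 0.95)

  expect_error(choose_test(list(c(1, 2), c(1, 2, 3))), "fewer than 3")
})

test_that("Kruskal-Wallis reproduces the rank-sum formula and conventions", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # two identical groups: H = 0, p = 1
  r2 <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # all values identical: convention H = 0, p = 1 with warning
  expect_warning(r3 <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2))), "identical")
  expect_equal(r3$p_value, 1)

  # invariance under strictly monotone transform
  s <- list(rlnorm(8), rlnorm(8), rlnorm(8))
  expect_equal(
    kruskal_wallis(s)$statistic,
    kruskal_wallis(purrr::map(s, ~ .x^3))$statistic
  )
})

test_that("one-way ANOVA matches the explicit mean-square formula", {
  set.seed(31)
  for (i in 1:20) {
    s <- purrr::map(1:3, ~ rnorm(sample(5:15, 1), mean = .x))
    r <- anova_oneway(s)
    x <- unlist(s)
    g <- rep(seq_along(s), lengths(s))
    grand <- mean(x)
    ssb <- sum(lengths(s) * (vapply(s, mean, 1) - grand)^2)
    ssw <- sum(unlist(purrr::map(s, ~ (.x - mean(.x))^2)))
    f <- (ssb / 2) / (ssw / (length(x) - 3))
    expect_equal(r$statistic, f, tolerance = 1e-10)
    expect_equal(r$p_value, pf(f, 2, length(x) - 3, lower.tail = FALSE),
      tolerance = 1e-10
    )
  }
  expect_error(anova_oneway(list(c(1, 1, 1), c(2, 2, 2))), "zero within-group")
})

test_that("BH and BY step-up adjustments match hand-worked examples", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.002)), c(0.02, 0.04, 0.04, 0.008))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_by(0.03), 0.03)
  # BY = BH scaled by c(3) = 1 + 1/2 + 1/3 = 11/6 here (no cap reached)
  expect_equal(adjust_by(c(0.01, 0.02, 0.03)), adjust_bh(c(0.01, 0.02, 0.03)) * 11 / 6)
  # ties: all equal p stay at p
  expect_equal(adjust_bh(rep(0.04, 6)), rep(0.04, 6))
  expect_error(adjust_bh(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(adjust_by(c(0.1, 1.4)), "\\(0, 1\\]")
})

test_that("adjustment dominance p <= BH <= BY holds on random vectors", {
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    bh <- adjust_bh(p)
    by <- adjust_by(p)
    expect_true(all(p <= bh + 1e-15))
    expect_true(all(bh <= by + 1e-15))
    expect_true(all(by <= 1))
  }
})

# independent oracle: full enumeration of the rank-sum statistic over all
# reassignments of the pooled values
pairwise_two_group_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  cmb <- utils::combn(length(pool), n1)
  us <- apply(cmb, 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], ">")) +
      0.5 * sum(outer(pool[idx], pool[-idx], "=="))
  })
  uobs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(1, 2 * min(mean(us <= uobs), mean(us >= uobs)))
}

test_that("Mann-Whitney agrees with exact enumeration for small groups", {
  set.seed(51)
  for (i in 1:10) {
    x <- round(rnorm(4), 3)
    y <- round(rnorm(4, 0.5), 3)
    got <- pairwise_two_group_oracle(x, y)
    mw <- steroidpanel:::mann_whitney(x, y)
    expect_equal(mw$p_value, got, tolerance = 1e-12)
  }

  # fully separated groups: U = 0 side, minimal exact p = 2/choose(20,10)
  mw <- steroidpanel:::mann_whitney(11:20, 1:10)
  expect_equal(mw$statistic, 100) # W = n1*n2 when x dominates
  # identical groups: p near 1
  mw2 <- steroidpanel:::mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(mw2$p_value, 0.99)
})

test_that("run_univariate returns 9 analyte tests and 27 pairwise rows", {
  cohort <- simulate_cohort(default_cohort_config(seed = 7))
  uv <- run_univariate(cohort, "female")
  expect_identical(nrow(uv$tests), 9L)
  expect_identical(nrow(uv$pairwise), 27L)
  expect_setequal(uv$tests$analyte, steroid_analytes())
  expect_true(all(uv$tests$p_unadjusted <= uv$tests$p_bh + 1e-15))
  expect_true(all(uv$tests$p_bh <= uv$tests$p_by + 1e-15))
  # group summary counts account for the stratum minus missing values
  n_female <- sum(cohort$sex == "female")
  for (i in seq_len(9)) {
    gs <- uv$tests$group_summaries[[i]]
    a <- uv$tests$analyte[i]
    n_miss <- sum(is.na(cohort[[a]][cohort$sex == "female"]))
    expect_identical(sum(gs$n), n_female - n_miss)
  }
  expect_error(run_univariate(cohort, "male", pairwise_family = "bogus"))

  # per-pair family option adjusts within each 9-analyte family
  uv2 <- run_univariate(cohort, "female", pairwise_family = "per_pair")
  one_pair <- dplyr::filter(uv2$pairwise, pair == "HC vs ME/CFSmm")
  expect_equal(one_pair$p_bh, adjust_bh(one_pair$p_unadjusted))
})

test_that("deleting aldosterone values changes only aldosterone results", {
  cohort <- simulate_cohort(default_cohort_config(seed = 13))
  mod <- cohort
  mod$aldosterone[mod$sex == "female"][1:5] <- NA
  uv1 <- run_univariate(cohort, "female")
  uv2 <- run_univariate(mod, "female")
  keep <- uv1$tests$analyte != "aldosterone"
  expect_equal(
    uv1$tests$p_unadjusted[keep],
    uv2$tests$p_unadjusted[keep]
  )
  keep_pw <- uv1$pairwise$analyte != "aldosterone"
  expect_equal(
    uv1$pairwise$p_unadjusted[keep_pw],
    uv2$pairwise$p_unadjusted[keep_pw]
  )
})

test_that("BH discovery rate is controlled under the global null", {
  set.seed(61)
  fdp <- replicate(150, {
    p <- vapply(1:9, function(i) {
      s <- purrr::map(1:3, ~ rlnorm(15))
      kruskal_wallis(s)$p_value
    }, numeric(1))
    mean(adjust_bh(p) <= 0.05)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(length(fdp)) + 0.01)
})

test_that("a 3x shifted analyte is reliably BH-detected", {
  set.seed(62)
  hits <- replicate(50, {
    cfg <- default_cohort_config(seed = sample.int(1e6, 1))
    mg <- cfg$marginals
    shift <- mg$sex == "female" & mg$group == "ME/CFSsa" &
      mg$analyte == "progesterone"
    mg$mu_log[shift] <- mg$mu_log[shift] + log(3)
    cfg2 <- cohort_config(
      cfg$group_sizes, mg, cfg$spearman_targets,
      stats::setNames(numeric(0), character(0)), cfg$seed
    )
    uv <- run_univariate(simulate_cohort(cfg2), "female")
    uv$tests$p_bh[uv$tests$analyte == "progesterone"] <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})
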
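# Classifier evaluation: PLS-DA internals, LOO/OOB probabilities, ROC and
# optimal cutpoint.

test_that("first PLS weight vector is proportional to X'y", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(15:40, 1)
    p <- sample(3:9, 1)
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("v", 1:p)
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    while (length(unique(y)) < 2) y <- factor(sample(c("a", "b"), n, replace = TRUE))
    fit <- fit_plsda(X, y, n_components = 1)
    Xs <- scale(X)
    yv <- ifelse(as.integer(y) == 2, 1, -1)
    yv <- yv - mean(yv)
    w_ref <- drop(crossprod(Xs, yv))
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    cos_sim <- abs(sum(w_ref * fit$weights[, 1]))
    expect_gte(cos_sim, 1 - 1e-8)
  }
})

test_that("two-component PLS scores are orthogonal and rank is enforced", {
  set.seed(82)
  X <- matrix(rnorm(30 * 5), 30)
  colnames(X) <- paste0("v", 1:5)
  y <- factor(rep(c("a", "b"), 15))
  fit <- fit_plsda(X, y, n_components = 2)
  expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)

  # rank-1 predictors cannot support 2 components
  X1 <- cbind(v1 = rnorm(20), v2 = 0)
  X1[, 2] <- 2 * X1[, 1]
  colnames(X1) <- c("v1", "v2")
  expect_error(
    fit_plsda(X1, factor(rep(c("a", "b"), 10)), n_components = 2),
    "rank"
  )

  # zero-variance column dropped with a warning
  X2 <- cbind(X, cst = 1)
  expect_warning(fit2 <- fit_plsda(X2, y, n_components = 1), "zero-variance")
  expect_identical(length(fit2$kept_columns), 5L)
})

test_that("a class-leaking predictor yields near-perfect LOO AUC", {
  set.seed(83)
  cohort <- simulate_cohort(default_cohort_config(seed = 83))
  leaky <- cohort
  leaky$cortisone <- ifelse(leaky$group == "HC", 1, 2) * exp(rnorm(nrow(leaky), 0, 0.01))
  probs <- loo_probabilities(leaky, "female", classifier_spec("plsda", n_components = 1))
  r <- roc_curve(probs$prob, probs$y)
  expect_gte(r$auc, 0.99)
})

test_that("LOO probabilities equal an explicit per-fold manual refit", {
  set.seed(84)
  cfg <- cohort_config(
    group_sizes = tibble::tibble(
      sex = "female", group = c("HC", "ME/CFSmm"), n = c(6L, 6L)
    ),
    marginals = default_marginals(),
    spearman_targets = default_spearman_targets(),
    missing_rates = stats::setNames(numeric(0), character(0)),
    seed = 84L
  )
  cohort <- simulate_cohort(cfg)
  X <- as.matrix(cohort[, steroid_analytes()])
  y <- factor(ifelse(cohort$group == "HC", "HC", "ME/CFS"), levels = c("HC", "ME/CFS"))

  for (method in c("lda", "plsda")) {
    spec <- classifier_spec(method, n_components = 1)
    got <- loo_probabilities(cohort, "female", spec)
    manual <- vapply(seq_len(nrow(X)), function(i) {
      Ltr <- log(X[-i, , drop = FALSE])
      ctr <- colMeans(Ltr)
      scl <- apply(Ltr, 2, sd)
      Xtr <- scale(Ltr, ctr, scl)
      Xte <- scale(log(X[i, , drop = FALSE]), ctr, scl)
      if (method == "lda") {
        fit <- MASS::lda(Xtr, grouping = y[-i])
        unname(predict(fit, Xte)$posterior[, "ME/CFS"])
      } else {
        fit <- fit_plsda(Xtr, y[-i], n_components = 1)
        predict(fit, Xte, type = "prob")
      }
    }, numeric(1))
    expect_equal(got$prob, manual, tolerance = 1e-10)
  }
})

test_that("well-separated classes put every LOO probability on the right side", {
  set.seed(85)
  cohort <- simulate_cohort(default_cohort_config(seed = 85))
  sep <- dplyr::filter(cohort, sex == "male")
  sep$testosterone <- ifelse(sep$group == "HC", 1, 50) * exp(rnorm(nrow(sep), 0, 0.05))
  for (method in c("lda", "plsda")) {
    probs <- loo_probabilities(sep, "male", classifier_spec(method, n_components = 2))
    expect_true(all(probs$prob[probs$y == "ME/CFS"] > 0.5))
    expect_true(all(probs$prob[probs$y == "HC"] < 0.5))
  }
})

test_that("forest OOB probabilities are seeded and separate a clean signal", {
  cohort <- simulate_cohort(default_cohort_config(seed = 86))
  spec <- classifier_spec("forest", n_trees = 500)
  p1 <- forest_probabilities(cohort, "female", spec)
  p2 <- forest_probabilities(cohort, "female", spec)
  expect_identical(p1$prob, p2$prob)
  p3 <- forest_probabilities(cohort, "female", classifier_spec("forest", n_trees = 500, seed = 2))
  expect_false(identical(p1$prob, p3$prob))

  sep <- cohort
  sep$cortisol <- ifelse(sep$group == "HC", 1, 100)
  ps <- forest_probabilities(sep, "female", spec)
  acc <- mean((ps$prob >= 0.5) == (ps$y == "ME/CFS"))
  expect_gte(acc, 0.95)
})

test_that("trapezoid AUC equals the concordance count on random instances", {
  set.seed(87)
  for (i in 1:100) {
    n1 <- sample(3:20, 1)
    n0 <- sample(3:20, 1)
    probs <- round(runif(n1 + n0), sample(1:3, 1)) # induce ties
    y <- c(rep(1, n1), rep(0, n0))
    r <- roc_curve(probs, y)
    expect_equal(r$auc, auc_by_counting(probs, y), tolerance = 1e-12)
  }
  # boundary conventions
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_curve(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("optimal cutoff minimizes distance to (0,1) with the stated tie-break", {
  # curve containing the perfect point
  r <- manual_roc(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  oc <- optimal_cutoff(r)
  expect_equal(oc$distance, 0)
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)

  # symmetric two-point tie: equal distances, tie-break selects higher Se
  r2 <- manual_roc(fpr = c(0.2, 0.4), tpr = c(0.6, 0.8))
  oc2 <- optimal_cutoff(r2)
  expect_equal(oc2$sensitivity, 0.8)
  expect_equal(oc2$specificity, 0.6)

  # random curves: equals exhaustive search
  set.seed(88)
  for (i in 1:100) {
    k <- sample(3:15, 1)
    fpr <- sort(runif(k))
    tpr <- sort(runif(k))
    r3 <- manual_roc(fpr, tpr)
    oc3 <- optimal_cutoff(r3)
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    expect_equal(oc3$distance, min(d), tolerance = 1e-12)
  }
})

test_that("evaluation composes the pieces with exact accuracy identity", {
  cohort <- simulate_cohort(default_cohort_config(seed = 89))
  ev <- evaluate_classifier(cohort, "male", classifier_spec("plsda", n_components = 2))
  expect_equal(
    ev$accuracy * (ev$n_cases + ev$n_controls),
    ev$sensitivity * ev$n_cases + ev$specificity * ev$n_controls,
    tolerance = 1e-12
  )
  probs <- tidy(ev)
  expect_identical(nrow(probs), ev$n_cases + ev$n_controls)
  expect_true(all(probs$prob >= 0 & probs$prob <= 1))

  # label inversion maps AUC to 1 - AUC
  r <- roc_curve(probs$prob, probs$y == "ME/CFS")
  r_inv <- roc_curve(probs$prob, probs$y == "HC")
  expect_equal(r_inv$auc, 1 - r$auc, tolerance = 1e-12)

  # full panel has the four expected rows
  tbl <- evaluate_all_classifiers(cohort, "male", n_trees = 300, seed = 1)
  expect_identical(nrow(tbl), 4L)
  expect_setequal(tbl$method, c("lda", "forest", "plsda"))
  expect_true(all(tbl$auc >= 0 & tbl$auc <= 1))
})

test_that("aldosterone-missing subjects are dropped and counted", {
  cohort <- simulate_cohort(default_cohort_config(seed = 90))
  n_missing <- sum(is.na(cohort$aldosterone[cohort$sex == "female"]))
  probs <- loo_probabilities(cohort, "female", classifier_spec("lda"))
  expect_identical(attr(probs, "n_dropped"), n_missing)
  expect_identical(nrow(probs), sum(cohort$sex == "female") - n_missing)
})
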
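# Disease-status prediction (HC vs ME/CFS, severity subgroups pooled) from
# the nine analytes: LDA and PLS-DA with leave-one-out probabilities, a
# bootstrap forest with out-of-bag probabilities, ROC and Table-3-style
# evaluation.

#' Specify a classifier
#'
#' @param method `"lda"`, `"forest"` or `"plsda"`.
#' @param n_components Latent components for PLS-DA (1 or 2).
#' @param n_trees Trees for the bootstrap forest (default 10,000).
#' @param seed Seed for the forest's bootstrap resampling.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("lda", "forest", "plsda"),
                            n_components = 2, n_trees = 10000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_components %in% c(1, 2), n_trees >= 1)
  structure(
    list(
      method = method, n_components = as.integer(n_components),
      n_trees = as.integer(n_trees), seed = as.integer(seed)
    ),
    class = "classifier_spec"
  )
}

# Complete-case design matrix for one sex stratum. Cases are ME/CFS (mm and
# sa pooled); subjects with any missing predictor are dropped (count kept).
stratum_design <- function(cohort, sex) {
  cohort <- validate_cohort_table(cohort)
  stratum <- cohort[cohort$sex == sex, , drop = FALSE]
  if (nrow(stratum) == 0) stop("no subjects in stratum '", sex, "'", call. = FALSE)
  X <- as.matrix(stratum[, steroid_analytes()])
  complete <- stats::complete.cases(X)
  y <- factor(
    ifelse(stratum$group == "HC", "HC", "ME/CFS"),
    levels = c("HC", "ME/CFS")
  )
  list(
    X = X[complete, , drop = FALSE],
    y = y[complete],
    subject_id = stratum$subject_id[complete],
    n_dropped = sum(!complete)
  )
}

# Per-fold preprocessing for LDA / PLS-DA: log then autoscale, parameters
# estimated on the training fold only. Constant training columns are
# dropped for the fold.
fold_preprocess <- function(X_train, X_test) {
  Lt <- log(X_train)
  Ls <- log(X_test)
  sds <- apply(Lt, 2, stats::sd)
  keep <- sds > 0
  ctr <- colMeans(Lt[, keep, drop = FALSE])
  scl <- sds[keep]
  list(
    train = scale(Lt[, keep, drop = FALSE], center = ctr, scale = scl),
    test = scale(Ls[, keep, drop = FALSE], center = ctr, scale = scl),
    dropped = colnames(X_train)[!keep]
  )
}

#' Leave-one-out class probabilities for LDA and PLS-DA
#'
#' For each subject the model is refitted on all other subjects — including
#' re-estimation of the log/autoscale preprocessing inside the fold — and
#' the held-out probability of being an ME/CFS case is recorded. LDA uses
#' empirical training-fold class frequencies as prior; PLS-DA uses the
#' NIPALS fit of [fit_plsda()] with its per-fold logistic calibration.
#' Deterministic.
#'
#' @param cohort A cohort tibble.
#' @param sex Stratum.
#' @param spec A [classifier_spec()] with method `"lda"` or `"plsda"`.
#' @return A tibble `subject_id`, `y` (factor), `prob` (probability of
#'   ME/CFS), with attributes `provenance = "leave-one-out"` and
#'   `n_dropped`.
#' @export
loo_probabilities <- function(cohort, sex, spec) {
  stopifnot(inherits(spec, "classifier_spec"), spec$method %in% c("lda", "plsda"))
  d <- stratum_design(cohort, sex)
  if (min(table(d$y)) < 2) {
    stop("each class needs >= 2 subjects for leave-one-out", call. = FALSE)
  }
  n <- nrow(d$X)
  dropped_cols <- character()
  prob <- vapply(seq_len(n), function(i) {
    ytr <- d$y[-i]
    if (length(unique(ytr)) < 2) {
      stop("a leave-one-out fold has a single-class training set", call. = FALSE)
    }
    pp <- fold_preprocess(d$X[-i, , drop = FALSE], d$X[i, , drop = FALSE])
    if (length(pp$dropped)) dropped_cols <<- union(dropped_cols, pp$dropped)
    if (spec$method == "lda") {
      fit <- MASS::lda(pp$train, grouping = ytr)
      unname(stats::predict(fit, pp$test)$posterior[, "ME/CFS"])
    } else {
      fit <- fit_plsda(pp$train, ytr, n_components = spec$n_components)
      predict(fit, pp$test, type = "prob")
    }
  }, numeric(1))
  out <- tibble::tibble(subject_id = d$subject_id, y = d$y, prob = prob)
  attr(out, "provenance") <- "leave-one-out"
  attr(out, "n_dropped") <- d$n_dropped
  attr(out, "dropped_columns") <- dropped_cols
  out
}

#' Out-of-bag class probabilities from a bootstrap forest
#'
#' Fits a random forest (default 10,000 trees, sqrt(p) candidate features
#' per split, unlimited depth) on the raw concentrations and reads each
#' subject's probability of ME/CFS from the out-of-bag votes: the fraction
#' of trees whose bootstrap sample excluded the subject that vote ME/CFS.
#' Reproducible given `spec$seed`.
#'
#' @inheritParams loo_probabilities
#' @param spec A [classifier_spec()] with method `"forest"`.
#' @return As [loo_probabilities()], with `provenance = "out-of-bag"`.
#' @export
forest_probabilities <- function(cohort, sex, spec) {
  stopifnot(inherits(spec, "classifier_spec"), spec$method == "forest")
  d <- stratum_design(cohort, sex)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  rf <- randomForest::randomForest(
    x = d$X, y = d$y, ntree = spec$n_trees, importance = FALSE
  )
  prob <- rf$votes[, "ME/CFS"]
  if (anyNA(prob)) {
    stop("some subject was in-bag for every tree; increase n_trees", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = d$subject_id, y = d$y, prob = unname(prob))
  attr(out, "provenance") <- "out-of-bag"
  attr(out, "n_dropped") <- d$n_dropped
  out
}

#' Evaluate a classifier on a sex stratum
#'
#' Composes the probability estimate (leave-one-out for LDA/PLS-DA,
#' out-of-bag for the forest), the ROC curve, the closest-to-(0,1) cutoff
#' and the resulting accuracy, sensitivity (cases correct) and specificity
#' (controls correct). Accuracy satisfies
#' `accuracy * n = Se * n_cases + Sp * n_controls` exactly.
#'
#' @inheritParams loo_probabilities
#' @param spec A [classifier_spec()].
#' @return A one-row tibble of class `classifier_evaluation`: `sex`,
#'   `method`, `n_components`, `auc`, `cutoff`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_cases`, `n_controls`, `n_dropped`; the per-subject
#'   probabilities and the `roc_result` are attached as attributes
#'   `probabilities` and `roc`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' evaluate_classifier(cohort, "male", classifier_spec("lda"))
evaluate_classifier <- function(cohort, sex, spec) {
  probs <- if (spec$method == "forest") {
    forest_probabilities(cohort, sex, spec)
  } else {
    loo_probabilities(cohort, sex, spec)
  }
  roc <- roc_curve(probs$prob, probs$y)
  cut <- optimal_cutoff(roc)
  acc <- (cut$sensitivity * roc$n_cases + cut$specificity * roc$n_controls) /
    (roc$n_cases + roc$n_controls)
  out <- tibble::tibble(
    sex = sex,
    method = spec$method,
    n_components = if (spec$method == "plsda") spec$n_components else NA_integer_,
    auc = roc$auc,
    cutoff = cut$cutoff,
    accuracy = acc,
    sensitivity = cut$sensitivity,
    specificity = cut$specificity,
    n_cases = roc$n_cases,
    n_controls = roc$n_controls,
    n_dropped = attr(probs, "n_dropped")
  )
  attr(out, "probabilities") <- probs
  attr(out, "roc") <- roc
  class(out) <- c("classifier_evaluation", class(out))
  out
}

#' Evaluate the full classifier panel on a stratum
#'
#' Runs LDA, the bootstrap forest and PLS-DA with one and two components,
#' returning one row per classifier in the shape of the study's evaluation
#' table (AUC, accuracy, sensitivity, specificity).
#'
#' @inheritParams loo_probabilities
#' @param n_trees Trees for the forest.
#' @param seed Seed for the forest bootstrap.
#' @return A tibble with four rows.
#' @export
evaluate_all_classifiers <- function(cohort, sex, n_trees = 10000L, seed = 1L) {
  specs <- list(
    classifier_spec("lda", seed = seed),
    classifier_spec("forest", n_trees = n_trees, seed = seed),
    classifier_spec("plsda", n_components = 1, seed = seed),
    classifier_spec("plsda", n_components = 2, seed = seed)
  )
  purrr::map_dfr(specs, function(s) {
    ev <- evaluate_classifier(cohort, sex, s)
    attr(ev, "probabilities") <- NULL
    attr(ev, "roc") <- NULL
    class(ev) <- setdiff(class(ev), "classifier_evaluation")
    ev
  })
}
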
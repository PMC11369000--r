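# PLS-DA: NIPALS latent components against a +/-1 class code, with a
# logistic calibration from latent scores to class probabilities.

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis by the NIPALS scheme: the
#' predictors are column-centered and unit-scaled, the class is coded +/-1,
#' and each latent component takes its weight vector proportional to `X'y`
#' on the deflated data, scores `t = X w`, loadings `p = X't / t't`, with
#' rank-one deflation `X <- X - t p'`. Scores of successive components are
#' orthogonal. Class probabilities are calibrated by a logistic regression
#' of the class on the training scores — monotone, bounded and entirely
#' contained in the training data, so it can be re-estimated inside each
#' cross-validation fold. One or two components are supported; more invites
#' overfitting at these sample sizes.
#'
#' @param X Numeric matrix, subjects x analytes.
#' @param y Class labels: a factor with two levels or a logical/0-1 vector;
#'   the second level (or `TRUE`/1) is the positive class.
#' @param n_components 1 or 2.
#' @return An object of class `plsda` with elements `weights`, `loadings`,
#'   `scores`, `center`, `scale`, `calibration` (a glm), `kept_columns`.
#' @export
fit_plsda <- function(X, y, n_components = 2) {
  stopifnot(is.matrix(X), n_components %in% c(1, 2))
  y01 <- as_binary_class(y)
  if (length(unique(y01)) < 2) stop("y must contain both classes", call. = FALSE)
  stopifnot(nrow(X) == length(y01))

  sds <- apply(X, 2, stats::sd)
  kept <- sds > 0
  if (!all(kept)) {
    warning(
      "dropping zero-variance column(s): ",
      paste(colnames(X)[!kept], collapse = ", ")
    )
  }
  X <- X[, kept, drop = FALSE]
  if (n_components > qr(scale(X))$rank) {
    stop("n_components exceeds the rank of the scaled predictor matrix",
      call. = FALSE
    )
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Xd <- scale(X, center = ctr, scale = scl)
  yv <- ifelse(y01 == 1, 1, -1)
  yv <- yv - mean(yv)

  p_vars <- ncol(Xd)
  W <- P <- matrix(0, p_vars, n_components)
  Tm <- matrix(0, nrow(Xd), n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yv))
    w <- w / sqrt(sum(w^2))
    t_a <- drop(Xd %*% w)
    p_a <- drop(crossprod(Xd, t_a)) / sum(t_a^2)
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yv <- yv - t_a * sum(t_a * yv) / sum(t_a^2)
  }
  # weights for direct score computation from undeflated data
  Wstar <- W %*% solve(crossprod(P, W))

  calib_data <- as.data.frame(Tm)
  names(calib_data) <- paste0("X", seq_len(ncol(Tm)))
  calib_data$y <- y01
  calibration <- suppressWarnings(
    stats::glm(y ~ ., data = calib_data, family = stats::binomial())
  )
  structure(
    list(
      weights = W, loadings = P, scores = Tm, rotation = Wstar,
      center = ctr, scale = scl, calibration = calibration,
      kept_columns = which(kept), n_components = n_components
    ),
    class = "plsda"
  )
}

as_binary_class <- function(y) {
  if (is.factor(y)) {
    stopifnot(nlevels(y) == 2)
    as.integer(y) - 1L
  } else if (is.logical(y)) {
    as.integer(y)
  } else {
    stopifnot(all(y %in% c(0, 1)))
    as.integer(y)
  }
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda` fit.
#' @param newdata Numeric matrix with the same columns as the training data.
#' @param type `"prob"` (calibrated probability of the positive class) or
#'   `"scores"` (latent components).
#' @param ... Unused.
#' @export
predict.plsda <- function(object, newdata, type = c("prob", "scores"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$kept_columns, drop = FALSE]
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  scores <- Xs %*% object$rotation
  if (type == "scores") {
    return(scores)
  }
  nd <- as.data.frame(scores)
  names(nd) <- paste0("X", seq_len(ncol(scores)))
  unname(stats::predict(object$calibration, newdata = nd, type = "response"))
}
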
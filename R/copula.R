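# Gaussian-copula plumbing: Spearman -> Pearson conversion and PSD repair.

#' Convert a Spearman correlation to the Gaussian-copula Pearson correlation
#'
#' For a bivariate Gaussian copula with latent Pearson correlation r, the
#' Spearman correlation of the margins is (6/pi) * asin(r/2); inverting gives
#' r = 2 * sin(pi * rho_s / 6). Applied elementwise to a target Spearman
#' matrix this yields the latent correlation matrix to simulate from
#' (followed by [nearest_psd()] repair if the transform leaves the PSD cone).
#'
#' @param rho_s Spearman correlation(s) in \[-1, 1\]; vectors and matrices
#'   are transformed elementwise.
#' @return Latent Pearson correlation(s), same shape as the input.
#' @export
#' @examples
#' spearman_to_copula(c(0, 0.89, 1))
spearman_to_copula <- function(rho_s) {
  if (any(abs(rho_s) > 1 + 1e-12, na.rm = TRUE)) {
    stop("Spearman correlations must lie in [-1, 1]", call. = FALSE)
  }
  2 * sin(pi * pmax(pmin(rho_s, 1), -1) / 6)
}

#' Repair a symmetric matrix to the nearest unit-diagonal PSD matrix
#'
#' Eigenvalues below `eps` are clipped up to `eps`, the matrix is
#' reassembled and rescaled back to a unit diagonal. Matrices already
#' positive semi-definite are returned unchanged.
#'
#' @param mat Symmetric matrix.
#' @param eps Eigenvalue floor (default 1e-8).
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_psd <- function(mat, eps = 1e-8) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-10) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= eps) {
    return(mat)
  }
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}
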
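# PCA and Euclidean hierarchical clustering of the analyte panel.

# Preprocessed complete-case matrix shared by PCA and clustering. Raw ng/mL
# concentrations span three orders of magnitude across the panel, so the
# default is log then autoscale; both steps can be switched off.
panel_matrix <- function(cohort, log_transform = TRUE, autoscale = TRUE,
                         impute = c("none", "median")) {
  cohort <- validate_cohort_table(cohort)
  impute <- match.arg(impute)
  X <- as.matrix(cohort[, steroid_analytes()])
  rownames(X) <- cohort$subject_id
  if (impute == "median") {
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
    }
  }
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  if (log_transform) X <- log(X)
  if (autoscale) X <- scale(X)
  attr(X, "meta") <- list(
    log_transform = log_transform, autoscale = autoscale, impute = impute,
    n_dropped = sum(!complete)
  )
  X
}

#' Principal component analysis of the steroid panel
#'
#' Eigendecomposition (via [stats::prcomp()]) of the preprocessed panel:
#' complete-case subjects, log-transformed and autoscaled by default.
#' Components are ordered by decreasing variance; the sign of each loading
#' vector is fixed so its largest-magnitude entry is positive.
#'
#' @param cohort A cohort tibble.
#' @param log_transform,autoscale Preprocessing switches (both default
#'   `TRUE`). Unscaled PCA of raw ng/mL data is dominated by cortisol.
#' @param impute `"none"` (complete-case, default) or `"median"`
#'   (per-analyte median imputation before analysis).
#' @return An object of class `pca_result`: list with `scores` (tibble with
#'   `subject_id`, `sex`, `group`, `PC1..PCk`), `loadings` (matrix),
#'   `variance_fraction`, `meta`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' p <- run_pca(cohort)
#' round(p$variance_fraction, 3)
run_pca <- function(cohort, log_transform = TRUE, autoscale = TRUE,
                    impute = c("none", "median")) {
  cohort <- validate_cohort_table(cohort)
  X <- panel_matrix(cohort, log_transform, autoscale, impute)
  if (nrow(X) < 3) stop("need >= 3 complete-case subjects for PCA", call. = FALSE)
  pc <- stats::prcomp(X, center = !attr(X, "meta")$autoscale, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ids <- rownames(X)
  meta_rows <- cohort[match(ids, cohort$subject_id), c("subject_id", "sex", "group")]
  scores <- dplyr::bind_cols(meta_rows, tibble::as_tibble(pc$x))
  structure(
    list(
      scores = scores, loadings = pc$rotation,
      variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
      meta = attr(X, "meta")
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$scores), "subjects\n")
  cat(
    "  variance fractions:",
    paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n"
  )
  invisible(x)
}

#' Euclidean hierarchical clustering of subjects and analytes
#'
#' Agglomerative clustering (default complete linkage) under Euclidean
#' distance of the preprocessed panel (per-analyte z-scores of logged
#' concentrations by default, the standard metabolomics heatmap transform).
#' Both subject and analyte trees are built; cutting the subject tree at
#' `n_cuts` yields the requested number of groups.
#'
#' @inheritParams run_pca
#' @param n_cuts Number of subject clusters to cut (default 3).
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @return An object of class `clustering_result`: list with `subject_tree`
#'   and `analyte_tree` (hclust), `matrix` (preprocessed, reordered by leaf
#'   order), `clusters` (tibble `subject_id`, `cluster`), `meta`.
#' @export
hierarchical_cluster <- function(cohort, n_cuts = 3, linkage = c("complete", "average", "ward.D2"),
                                 log_transform = TRUE, autoscale = TRUE,
                                 impute = c("none", "median")) {
  linkage <- match.arg(linkage)
  X <- panel_matrix(cohort, log_transform, autoscale, impute)
  if (n_cuts > nrow(X)) stop("n_cuts exceeds the number of subjects", call. = FALSE)
  subject_tree <- stats::hclust(stats::dist(X), method = linkage)
  analyte_tree <- stats::hclust(stats::dist(t(X)), method = linkage)
  ordered <- X[subject_tree$order, analyte_tree$order, drop = FALSE]
  clusters <- stats::cutree(subject_tree, k = n_cuts)
  structure(
    list(
      subject_tree = subject_tree, analyte_tree = analyte_tree,
      matrix = ordered,
      clusters = tibble::tibble(
        subject_id = names(clusters), cluster = unname(clusters)
      ),
      meta = c(attr(X, "meta"), list(linkage = linkage, n_cuts = n_cuts))
    ),
    class = "clustering_result"
  )
}

#' Dendrogram as a Newick string
#'
#' @param clustering A `clustering_result`.
#' @param which `"subjects"` or `"analytes"`.
#' @return A Newick-format character scalar.
#' @export
dendrogram_newick <- function(clustering, which = c("subjects", "analytes")) {
  stopifnot(inherits(clustering, "clustering_result"))
  which <- match.arg(which)
  tree <- if (which == "subjects") clustering$subject_tree else clustering$analyte_tree
  ape::write.tree(ape::as.phylo(tree))
}

#' Export a clustering heatmap
#'
#' Writes the dendrogram-ordered matrix as CSV (deterministic,
#' byte-identical across runs for the same input) and, if \pkg{pheatmap}
#' is available, a PNG heatmap with the same row/column orders.
#'
#' @param clustering A `clustering_result`.
#' @param dir Output directory (created if needed).
#' @param basename Stem for the output files.
#' @return Invisibly, the paths written.
#' @export
export_heatmap <- function(clustering, dir, basename = "heatmap") {
  stopifnot(inherits(clustering, "clustering_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(basename, "_matrix.csv"))
  m <- tibble::as_tibble(clustering$matrix, rownames = "subject_id")
  readr::write_csv(m, csv)
  paths <- csv
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    png_path <- file.path(dir, paste0(basename, ".png"))
    pheatmap::pheatmap(
      t(clustering$matrix),
      cluster_rows = FALSE, cluster_cols = FALSE,
      filename = png_path, silent = TRUE
    )
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
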
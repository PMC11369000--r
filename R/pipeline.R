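# End-to-end orchestration: simulate/load -> univariate -> correlations ->
# classification -> unsupervised, with a machine-readable report bundle.

#' Configure a full pipeline run
#'
#' Bundles the input (a cohort tibble, a cohort CSV path, or a
#' [cohort_config()] to simulate from), the strata and stages to run, and
#' the statistical settings. The defaults are the study settings: FDR level
#' 0.05, B = 1000 permutations, 10,000 forest trees.
#'
#' @param input A cohort tibble, a path to a cohort CSV, or a
#'   `cohort_config` (simulated at run time).
#' @param strata Sexes to analyze.
#' @param stages Character subset of
#'   `c("univariate", "correlation", "classification", "unsupervised")`.
#' @param fdr_level FDR level in (0, 1).
#' @param B Permutation count for the Jennrich test (>= 99).
#' @param n_trees Forest size.
#' @param seed Integer master seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(input = default_cohort_config(),
                       strata = cohort_sexes(),
                       stages = c("univariate", "correlation", "classification", "unsupervised"),
                       fdr_level = 0.05, B = 1000L, n_trees = 10000L,
                       seed = 1L) {
  stopifnot(
    fdr_level > 0, fdr_level < 1, B >= 99,
    all(strata %in% cohort_sexes()),
    all(stages %in% c("univariate", "correlation", "classification", "unsupervised"))
  )
  structure(
    list(
      input = input, strata = strata, stages = stages,
      fdr_level = fdr_level, B = as.integer(B),
      n_trees = as.integer(n_trees), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

resolve_input <- function(input, seed) {
  if (inherits(input, "cohort_config")) {
    simulate_cohort(input)
  } else if (is.character(input)) {
    read_cohort(input)
  } else {
    validate_cohort_table(input)
  }
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage on every requested stratum and writes a
#' report bundle under `out_dir`: univariate and pairwise TSVs, per-group
#' Spearman matrices (CSV) with the strength-annotated edge list, the
#' Jennrich comparison TSV (HC vs pooled ME/CFS, with and without
#' aldosterone), the classifier evaluation TSV plus per-subject probability
#' CSVs, PCA scores/loadings CSVs, the subject dendrogram in Newick form and
#' the ordered heatmap matrix. A `manifest.json` records the configuration,
#' seed and every file written. A stage failure is recorded in the manifest
#' and the remaining stages continue.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest as a list (element `errors` is empty on
#'   a clean run).
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(default_cohort_config(seed = 1), B = 199L, n_trees = 500L)
#' manifest <- run_all(cfg, tempfile("bundle"))
#' }
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  errors <- list()
  note <- function(path) files <<- c(files, path)
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort <- resolve_input(config$input, config$seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  note(cohort_path)

  for (sx in config$strata) {
    tag <- sx

    if ("univariate" %in% config$stages) {
      try_stage(paste0("univariate_", sx), {
        uv <- run_univariate(cohort, sx)
        p1 <- file.path(out_dir, paste0("univariate_", tag, ".tsv"))
        readr::write_tsv(
          dplyr::select(uv$tests, -"group_summaries"), p1
        )
        note(p1)
        p2 <- file.path(out_dir, paste0("pairwise_", tag, ".tsv"))
        readr::write_tsv(uv$pairwise, p2)
        note(p2)
      })
    }

    if ("correlation" %in% config$stages) {
      try_stage(paste0("correlation_", sx), {
        edges <- purrr::map_dfr(cohort_groups(), function(g) {
          sm <- spearman_matrix(cohort, sx, g)
          pm <- file.path(out_dir, sprintf(
            "spearman_%s_%s.csv", tag, gsub("[^A-Za-z]", "", g)
          ))
          readr::write_csv(tibble::as_tibble(sm$rho, rownames = "analyte"), pm)
          note(pm)
          dplyr::mutate(correlation_edges(sm), sex = sx, group = g, .before = 1)
        })
        pe <- file.path(out_dir, paste0("correlation_edges_", tag, ".csv"))
        readr::write_csv(edges, pe)
        note(pe)

        comps <- purrr::map_dfr(c(TRUE, FALSE), function(incl) {
          jt <- jennrich_test(
            cohort, sx, "HC", c("ME/CFSmm", "ME/CFSsa"),
            include_aldosterone = incl, B = config$B, seed = config$seed
          )
          glance(jt)
        })
        pj <- file.path(out_dir, paste0("jennrich_", tag, ".tsv"))
        readr::write_tsv(comps, pj)
        note(pj)
      })
    }

    if ("classification" %in% config$stages) {
      try_stage(paste0("classification_", sx), {
        evals <- evaluate_all_classifiers(
          cohort, sx,
          n_trees = config$n_trees, seed = config$seed
        )
        pv <- file.path(out_dir, paste0("classifiers_", tag, ".tsv"))
        readr::write_tsv(evals, pv)
        note(pv)
        probs <- purrr::map_dfr(
          list(
            classifier_spec("lda", seed = config$seed),
            classifier_spec("forest", n_trees = config$n_trees, seed = config$seed),
            classifier_spec("plsda", n_components = 1, seed = config$seed),
            classifier_spec("plsda", n_components = 2, seed = config$seed)
          ),
          function(s) {
            p <- if (s$method == "forest") {
              forest_probabilities(cohort, sx, s)
            } else {
              loo_probabilities(cohort, sx, s)
            }
            dplyr::mutate(p,
              method = s$method,
              n_components = if (s$method == "plsda") s$n_components else NA_integer_,
              .before = 1
            )
          }
        )
        pp <- file.path(out_dir, paste0("probabilities_", tag, ".csv"))
        readr::write_csv(probs, pp)
        note(pp)
      })
    }

    if ("unsupervised" %in% config$stages) {
      try_stage(paste0("unsupervised_", sx), {
        stratum <- cohort[cohort$sex == sx, , drop = FALSE]
        pca <- run_pca(stratum)
        ps <- file.path(out_dir, paste0("pca_scores_", tag, ".csv"))
        readr::write_csv(pca$scores, ps)
        note(ps)
        pl <- file.path(out_dir, paste0("pca_loadings_", tag, ".csv"))
        readr::write_csv(
          tibble::as_tibble(pca$loadings, rownames = "analyte"), pl
        )
        note(pl)
        cl <- hierarchical_cluster(stratum)
        nw <- file.path(out_dir, paste0("dendrogram_", tag, ".nwk"))
        writeLines(dendrogram_newick(cl), nw)
        note(nw)
        hm <- export_heatmap(cl, out_dir, basename = paste0("heatmap_", tag))
        note(hm[1])
      })
    }
  }

  manifest <- list(
    config = list(
      strata = config$strata, stages = config$stages,
      fdr_level = config$fdr_level, B = config$B,
      n_trees = config$n_trees, seed = config$seed
    ),
    files = sort(basename(files)),
    errors = errors,
    package_version = as.character(utils::packageVersion("steroidpanel"))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
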
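# Cohort CSV round-trip and validation.

cohort_columns <- function() c("subject_id", "sex", "group", steroid_analytes())

#' Write / read a cohort CSV
#'
#' The on-disk format is a plain CSV with header
#' `subject_id,sex,group,<nine analyte columns>` in canonical order;
#' empty cells encode missing concentrations (ng/mL). The round-trip is
#' lossless including missingness.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort_table(cohort)
  readr::write_csv(cohort[, cohort_columns()], path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      group = readr::col_character(),
      .default = readr::col_character()
    ),
    na = character()
  )
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), cohort_columns())
  if (length(extra)) {
    stop("unknown columns in cohort file: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  for (a in steroid_analytes()) {
    v <- raw[[a]]
    bad <- which(v != "" & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric %s value at data row %d: '%s'", a, bad[1], v[bad[1]]
      ), call. = FALSE)
    }
    raw[[a]] <- ifelse(v == "", NA_real_, suppressWarnings(as.numeric(v)))
  }
  validate_cohort_table(raw[, cohort_columns()])
}

# Schema validation shared by IO and analysis entry points; returns the
# table with columns in canonical order or stops with a row-numbered error.
validate_cohort_table <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_sex <- which(!cohort$sex %in% cohort_sexes() | is.na(cohort$sex))
  if (length(bad_sex)) {
    stop(sprintf(
      "row %d: sex '%s' not one of: %s", bad_sex[1],
      cohort$sex[bad_sex[1]], paste(cohort_sexes(), collapse = ", ")
    ), call. = FALSE)
  }
  bad_group <- which(!cohort$group %in% cohort_groups() | is.na(cohort$group))
  if (length(bad_group)) {
    stop(sprintf(
      "row %d: group '%s' not one of: %s", bad_group[1],
      cohort$group[bad_group[1]], paste(cohort_groups(), collapse = ", ")
    ), call. = FALSE)
  }
  if (anyNA(cohort$subject_id) || anyDuplicated(cohort$subject_id)) {
    stop("subject_id must be present and unique", call. = FALSE)
  }
  for (a in steroid_analytes()) {
    bad <- which(!is.na(cohort[[a]]) & cohort[[a]] <= 0)
    if (length(bad)) {
      stop(sprintf("row %d: non-positive %s concentration", bad[1], a),
        call. = FALSE
      )
    }
  }
  tibble::as_tibble(cohort[, cohort_columns()])
}

#' Validate a cohort file or table and summarize its structure
#'
#' Runs the full schema check (fatal errors: unknown labels, non-positive or
#' non-numeric concentrations, duplicate ids) and reports per-stratum group
#' sizes and per-analyte missingness.
#'
#' @param source A file path or a cohort data frame.
#' @return A list with `cohort` (the validated tibble), `group_sizes`
#'   (tibble sex/group/n) and `missingness` (tibble analyte/n_missing/rate).
#' @export
validate_cohort <- function(source) {
  cohort <- if (is.character(source)) read_cohort(source) else validate_cohort_table(source)
  list(
    cohort = cohort,
    group_sizes = dplyr::count(cohort, .data$sex, .data$group, name = "n"),
    missingness = purrr::map_dfr(steroid_analytes(), function(a) {
      tibble::tibble(
        analyte = a,
        n_missing = sum(is.na(cohort[[a]])),
        rate = mean(is.na(cohort[[a]]))
      )
    })
  )
}
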
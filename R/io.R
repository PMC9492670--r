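# Readers/writers for the package's plain-text interchange formats:
# phenotype CSV, feature CSV with canonical edge-name header, per-subject
# time-series TSV, JSON sidecars.

#' Read a phenotype table
#'
#' @param path CSV with columns `subject_id`, `site`, `age`, `sex`, `group`
#'   and optional clinical columns (`medication`, `episode`,
#'   `education_years`, `illness_months`, `hdrs`).
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "site", "age", "sex", "group")
  missing <- setdiff(need, names(ph))
  if (length(missing) > 0) {
    abort(paste0("phenotype table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  ph$subject_id <- as.character(ph$subject_id)
  ph
}

#' Read a feature table (subjects x edges CSV)
#'
#' @param path CSV with a `subject_id` column and canonical edge-name
#'   headers.
#' @return Feature tibble.
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(ft)) abort("feature table lacks subject_id column")
  ft$subject_id <- as.character(ft$subject_id)
  ft
}

#' Read one subject's ROI time series (T x R TSV/CSV, header = region labels)
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return Numeric matrix (timepoints x regions).
#' @export
read_time_series <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as.matrix(df)
}

#' Write a synthetic cohort to disk
#'
#' Phenotypes as CSV, features as CSV with the canonical edge-name header
#' (edge mode) or one TSV per subject under `dir/time_series/` (time-series
#' mode), plus a JSON sidecar recording the generating configuration and
#' true parameters.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "phenotypes.csv")
  readr::write_csv(cohort$phenotypes, f)
  files <- c(files, f)
  if (!is.null(cohort$features)) {
    f <- file.path(dir, "features.csv")
    readr::write_csv(cohort$features, f)
    files <- c(files, f)
  }
  if (!is.null(cohort$time_series)) {
    tsdir <- file.path(dir, "time_series")
    dir.create(tsdir, showWarnings = FALSE)
    for (id in names(cohort$time_series)) {
      f <- file.path(tsdir, paste0(id, ".tsv"))
      readr::write_tsv(tibble::as_tibble(cohort$time_series[[id]],
                                         .name_repair = "minimal"), f)
      files <- c(files, f)
    }
  }
  sidecar <- list(
    config = unclass(cohort$config),
    true_params = list(
      delta_years = cohort$true_params$delta_years,
      medication_delta_years = cohort$true_params$medication_delta_years,
      mu = cohort$true_params$mu,
      beta = cohort$true_params$beta,
      gamma = cohort$true_params$gamma
    )
  )
  f <- file.path(dir, "cohort.json")
  jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Write pipeline run artifacts
#'
#' Persists the intermediate and final tables of a [run_pipeline()] result:
#' predictions CSV, Table-1-style metrics CSV, GLM coefficient CSVs,
#' subgroup comparison CSV, split JSON, the machine-readable summary JSON
#' and a MANIFEST listing every file (marked complete).
#'
#' @param run A `brainpad_run`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "brainpad_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(dir, name)
    readr::write_csv(df, f)
    files <<- c(files, f)
  }
  put_csv(run$predictions, "predictions.csv")
  put_csv(run$metrics, "metrics.csv")
  if (!is.null(run$glm_main)) put_csv(tidy(run$glm_main), "glm_main.csv")
  if (!is.null(run$glm_clinical)) put_csv(tidy(run$glm_clinical), "glm_clinical.csv")
  if (!is.null(run$subgroups)) put_csv(run$subgroups, "subgroup_comparisons.csv")
  if (!is.null(run$correlations)) put_csv(run$correlations, "clinical_correlations.csv")
  put_csv(run$importance, "feature_importance.csv")
  f <- file.path(dir, "split.json")
  jsonlite::write_json(
    list(train_ids = run$split$train_ids, holdout_ids = run$split$holdout_ids,
         test_ids = run$split$test_ids),
    f, auto_unbox = FALSE
  )
  files <- c(files, f)
  f <- file.path(dir, "summary.json")
  writeLines(run$summary_json, f)
  files <- c(files, f)
  f <- file.path(dir, "MANIFEST")
  writeLines(c("status: complete", basename(files)), f)
  files <- c(files, f)
  invisible(files)
}
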
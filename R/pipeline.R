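#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort), `"features"` (precomputed
#'   edge features) or `"time_series"` (per-subject ROI series).
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param features,phenotypes In-memory tables (features / time_series
#'   mode); alternatively `features_path` / `phenotypes_path` /
#'   `time_series_dir` to read from disk.
#' @param features_path,phenotypes_path,time_series_dir File inputs.
#' @param harmonization `"zscore"` (per-subject, default), `"zscore_site"`,
#'   `"combat"`, or `"none"`.
#' @param combat_protect Covariates protected by ComBat harmonization.
#' @param learners Base learner kinds.
#' @param k Cross-validation fold count.
#' @param holdout_fraction Control hold-out fraction.
#' @param clinical_stats Run the clinical GLM / subgroup battery on
#'   patients (default `TRUE`; skipped automatically when the columns are
#'   absent).
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param output_dir If non-NULL, artifacts are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "features", "time_series"),
                       synthetic = NULL,
                       features = NULL, phenotypes = NULL,
                       features_path = NULL, phenotypes_path = NULL,
                       time_series_dir = NULL,
                       harmonization = c("zscore", "zscore_site", "combat", "none"),
                       combat_protect = c("age", "sex", "group"),
                       learners = learner_kinds(),
                       k = 5, holdout_fraction = 0.2,
                       clinical_stats = TRUE,
                       seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  harmonization <- harmonization[1]
  if (!harmonization %in% c("zscore", "zscore_site", "combat", "none")) {
    abort(sprintf(
      "unknown harmonization '%s' (use zscore, zscore_site, combat or none)",
      harmonization
    ))
  }
  learners <- match.arg(learners, learner_kinds(), several.ok = TRUE)
  if (mode == "synthetic") {
    if (is.null(synthetic)) abort("synthetic mode requires a synthetic_config")
    if (!inherits(synthetic, "synthetic_config")) {
      synthetic <- do.call(synthetic_config, as.list(synthetic))
    }
  } else {
    # in time_series mode, `features` holds the named list of series
    has_mem <- !is.null(phenotypes) && !is.null(features)
    has_path <- !is.null(phenotypes_path) &&
      (!is.null(features_path) || !is.null(time_series_dir))
    if (!has_mem && !has_path) {
      abort(sprintf("%s mode requires in-memory tables or file paths", mode))
    }
  }
  structure(list(
    mode = mode, synthetic = synthetic,
    features = features, phenotypes = phenotypes,
    features_path = features_path, phenotypes_path = phenotypes_path,
    time_series_dir = time_series_dir,
    harmonization = harmonization, combat_protect = combat_protect,
    learners = learners, k = as.integer(k),
    holdout_fraction = holdout_fraction,
    clinical_stats = isTRUE(clinical_stats),
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks table alignment, required columns, missing-value census, per-site
#' counts and the age range. Always returns the full diagnostics table;
#' rows with `severity == "fatal"` would stop [run_pipeline()].
#'
#' @param features Feature tibble (or `NULL` in time-series mode).
#' @param phenotypes Phenotype tibble.
#' @return Tibble with columns `severity` (`"fatal"`/`"warning"`), `check`,
#'   `message`.
#' @export
validate_inputs <- function(features, phenotypes) {
  out <- list()
  note <- function(severity, check, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message
    )
  }
  need <- c("subject_id", "site", "age", "group")
  missing <- setdiff(need, names(phenotypes))
  if (length(missing) > 0) {
    note("fatal", "phenotype_columns",
         paste0("missing column(s): ", paste(missing, collapse = ", ")))
    return(dplyr::bind_rows(out))
  }
  if (anyDuplicated(phenotypes$subject_id)) {
    note("fatal", "subject_ids", "duplicated subject ids in phenotypes")
  }
  if (anyNA(phenotypes$age) || anyNA(phenotypes$site) || anyNA(phenotypes$group)) {
    note("fatal", "missing_values", "missing values in site/age/group")
  } else {
    if (min(phenotypes$age) < 0 || max(phenotypes$age) > 120) {
      note("warning", "age_range", "ages outside 0-120 years")
    }
    ctrl_per_site <- table(phenotypes$site[phenotypes$group == "control"])
    lone <- names(ctrl_per_site)[ctrl_per_site == 1]
    if (length(lone) > 0) {
      note("warning", "site_counts",
           paste0("site(s) with a single control (go to training per split policy): ",
                  paste(lone, collapse = ", ")))
    }
    if (sum(phenotypes$group == "control") == 0) {
      note("fatal", "groups", "no control subjects")
    }
  }
  if (!is.null(features)) {
    if (!"subject_id" %in% names(features)) {
      note("fatal", "feature_columns", "feature table lacks subject_id")
    } else {
      fid <- as.character(features$subject_id)
      pid <- as.character(phenotypes$subject_id)
      if (length(fid) != length(pid) || !all(fid == pid)) {
        unmatched <- setdiff(pid, fid)
        note("fatal", "alignment",
             if (length(unmatched) > 0) {
               paste0("phenotype row(s) without matching feature row: ",
                      paste(head(unmatched, 5), collapse = ", "))
             } else "feature/phenotype rows not aligned")
      }
      fm <- features[setdiff(names(features), "subject_id")]
      if (anyNA(fm)) note("fatal", "missing_values", "missing feature values")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(severity = character(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}

#' Run the full brain-age pipeline
#'
#' Executes the analysis chain: acquire data (synthetic generation, edge
#' features or ROI time series), harmonize site effects, split controls
#' into training and hold-out sets, fit the stacked age model on training
#' controls, predict hold-out controls and patients, fit the age-bias
#' correction on the hold-out set, derive brain-PAD scores, and run the
#' statistical battery (corrected and uncorrected group comparison, main
#' GLM with sex/diagnosis/age/age-squared, clinical GLM and subgroup
#' comparisons with FDR, Spearman correlations). Identical config + seed
#' gives an identical summary.
#'
#' @param config A [run_config()].
#' @return A list of class `brainpad_run`: `predictions`, `metrics`
#'   (Table-1-style fold-wise metrics), `bias`, `comparison_corrected`,
#'   `comparison_uncorrected`, `glm_main`, `glm_clinical`, `subgroups`,
#'   `correlations`, `importance`, `edge_age`, `split`, `diagnostics`,
#'   `log`, `summary_json` (canonical serialization) and, when
#'   `output_dir` was set, `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  log <- list()
  log_stage <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, message = msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(c(sprintf("status: incomplete (failed at stage '%s')", name),
                     conditionMessage(e)),
                   file.path(config$output_dir, "MANIFEST"))
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  seed <- config$seed

  # --- stage: input -----------------------------------------------------
  acquired <- stage("input", {
    if (config$mode == "synthetic") {
      cohort <- generate_cohort(config$synthetic)
      feats <- cohort$features
      ph <- cohort$phenotypes
      if (is.null(feats)) {
        feats <- build_feature_table(cohort$time_series)
      }
      list(features = feats, phenotypes = ph)
    } else {
      ph <- config$phenotypes %||% read_phenotypes(config$phenotypes_path)
      if (config$mode == "features") {
        feats <- config$features %||% read_feature_table(config$features_path)
      } else {
        series <- config$features # unused slot in this mode
        if (!is.null(config$time_series_dir)) {
          paths <- list.files(config$time_series_dir, pattern = "\\.(tsv|csv|txt)$",
                              full.names = TRUE)
          ids <- sub("\\.[^.]+$", "", basename(paths))
          series <- setNames(lapply(paths, read_time_series), ids)
          series <- series[as.character(ph$subject_id)]
        }
        feats <- build_feature_table(series)
      }
      list(features = feats, phenotypes = ph)
    }
  })
  features <- acquired$features
  phenotypes <- acquired$phenotypes
  log_stage("input", sprintf("%d subjects x %d edges",
                             nrow(features), ncol(features) - 1L))

  # --- stage: validate --------------------------------------------------
  diagnostics <- validate_inputs(features, phenotypes)
  if (any(diagnostics$severity == "fatal")) {
    stage("validate", abort(paste(
      diagnostics$message[diagnostics$severity == "fatal"], collapse = "; "
    )))
  }

  # --- stage: harmonize -------------------------------------------------
  features_h <- stage("harmonize", {
    switch(config$harmonization,
      zscore = harmonize_zscore(features),
      zscore_site = harmonize_zscore_site(features, phenotypes),
      combat = harmonize_combat(features, phenotypes,
                                protect = config$combat_protect)$features,
      none = features
    )
  })
  log_stage("harmonize", config$harmonization)

  # --- stage: split -----------------------------------------------------
  split <- stage("split", make_split(phenotypes, config$holdout_fraction,
                                     seed = seed + 1L))
  log_stage("split", sprintf("train %d / holdout %d / test %d",
                             split$counts["train"], split$counts["holdout"],
                             split$counts["test"]))

  idx_of <- function(ids) match(ids, phenotypes$subject_id)
  tr <- idx_of(split$train_ids)
  ho <- idx_of(split$holdout_ids)
  te <- idx_of(split$test_ids)

  # --- stage: train -----------------------------------------------------
  model <- stage("train", fit_brainage(
    features_h[tr, , drop = FALSE], phenotypes$age[tr],
    learners = config$learners, k = config$k, seed = seed + 2L
  ))
  log_stage("train", sprintf("%d training controls, learners: %s",
                             length(tr), paste(config$learners, collapse = ", ")))

  # --- stage: predict ---------------------------------------------------
  pred <- stage("predict", {
    metrics <- dplyr::bind_rows(
      metrics_by_fold(model, features_h[ho, , drop = FALSE],
                      phenotypes$age[ho], "validation"),
      if (length(te) > 0) {
        metrics_by_fold(model, features_h[te, , drop = FALSE],
                        phenotypes$age[te], "test")
      }
    )
    list(
      holdout = predict(model, features_h[ho, , drop = FALSE]),
      test = if (length(te) > 0) predict(model, features_h[te, , drop = FALSE]),
      metrics = metrics
    )
  })

  # --- stage: bias ------------------------------------------------------
  bias <- stage("bias", fit_bias(pred$holdout, phenotypes$age[ho]))
  keep_cols <- intersect(
    c("subject_id", "site", "age", "sex", "group", "medication", "episode",
      "education_years", "illness_months", "hdrs"),
    names(phenotypes)
  )
  predictions <- stage("bias", dplyr::bind_rows(
    apply_bias(bias, phenotypes[ho, keep_cols], pred = pred$holdout),
    if (length(te) > 0) apply_bias(bias, phenotypes[te, keep_cols], pred = pred$test)
  ))
  log_stage("bias", sprintf("slope %.4f intercept %.4f on %d hold-out controls",
                            bias$slope, bias$intercept, bias$n))

  # --- stage: stats -----------------------------------------------------
  stats_out <- stage("stats", pipeline_stats(predictions, config))
  log_stage("stats", sprintf("%d subgroup comparisons",
                             if (is.null(stats_out$subgroups)) 0L
                             else nrow(stats_out$subgroups)))

  # --- stage: importance ------------------------------------------------
  importance <- stage("importance", feature_importance(model, top_n = 20))
  edge_age <- stage("importance",
                    edge_age_correlations(features_h[tr, , drop = FALSE],
                                          phenotypes$age[tr]))

  run <- structure(list(
    config = config, split = split, model = model, bias = bias,
    predictions = predictions, metrics = pred$metrics,
    comparison_corrected = stats_out$comparison_corrected,
    comparison_uncorrected = stats_out$comparison_uncorrected,
    glm_main = stats_out$glm_main, glm_clinical = stats_out$glm_clinical,
    subgroups = stats_out$subgroups, correlations = stats_out$correlations,
    importance = importance, edge_age = edge_age,
    diagnostics = diagnostics, log = dplyr::bind_rows(log)
  ), class = "brainpad_run")
  run$summary_json <- summarize_run_json(run)

  if (!is.null(config$output_dir)) {
    run$files <- stage("write", write_run(run, config$output_dir))
  }
  run
}

# The statistical battery on the prediction table.
pipeline_stats <- function(predictions, config) {
  out <- list()
  grp <- factor(ifelse(predictions$group == "control", "control", "patient"),
                levels = c("control", "patient"))
  df <- predictions
  df$group2 <- grp
  has_patients <- any(grp == "patient")
  if (has_patients && sum(grp == "control") >= 2 && sum(grp == "patient") >= 2) {
    out$comparison_corrected <- compare_groups(df, brain_pad, group2)
    df_unc <- df
    df_unc$pad_uncorrected <- df$raw_pred - df$age
    out$comparison_uncorrected <- compare_groups(df_unc, pad_uncorrected, group2)
    out$glm_main <- try_or_null(glm_brainpad(
      df, terms = c("sex", "group2", "age", "age2"), response = "brain_pad"
    ))
  }
  if (config$clinical_stats && has_patients) {
    pat <- df[df$group2 == "patient", , drop = FALSE]
    clin_terms <- intersect(
      c("sex", "episode", "medication", "age", "education_years", "illness_months"),
      names(pat)
    )
    usable <- clin_terms[vapply(clin_terms, function(tm) {
      v <- pat[[tm]][!is.na(pat[[tm]])]
      length(unique(v)) >= 2
    }, logical(1))]
    if (all(c("age") %in% usable) && length(usable) >= 3) {
      out$glm_clinical <- try_or_null(glm_brainpad(
        pat, terms = c(setdiff(usable, "age"), "age", "age2"),
        response = "brain_pad"
      ))
    }
    out$subgroups <- subgroup_battery(pat)
    out$correlations <- clinical_correlations(pat)
  }
  out
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

# Subgroup comparisons among patients: medication, episode, sex, and
# median splits of education years and illness months; BH-FDR across the
# battery.
subgroup_battery <- function(pat) {
  rows <- list()
  add <- function(label, cmp_data, pad_col, grp_col) {
    cmp <- try_or_null(compare_groups(cmp_data, !!rlang::sym(pad_col),
                                      !!rlang::sym(grp_col)))
    if (is.null(cmp)) return(invisible(NULL))
    row <- tidy(cmp)
    row <- dplyr::bind_cols(tibble::tibble(comparison = label), row)
    rows[[length(rows) + 1]] <<- row
  }
  if ("medication" %in% names(pat)) {
    d <- pat[!is.na(pat$medication), , drop = FALSE]
    if (nrow(d) > 3) {
      d$medication_status <- factor(ifelse(d$medication == 1, "medicated", "unmedicated"),
                                    levels = c("unmedicated", "medicated"))
      add("medication", d, "brain_pad", "medication_status")
    }
  }
  if ("episode" %in% names(pat)) {
    d <- pat[!is.na(pat$episode), , drop = FALSE]
    if (nrow(d) > 3) add("episode", d, "brain_pad", "episode")
  }
  if ("sex" %in% names(pat)) add("sex", pat, "brain_pad", "sex")
  for (col in c("education_years", "illness_months")) {
    if (!col %in% names(pat)) next
    d <- try_or_null(median_split(pat, !!rlang::sym(col)))
    if (is.null(d)) next
    add(paste0(col, "_median_split"), d, "brain_pad", "subgroup")
  }
  if (length(rows) == 0) return(NULL)
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_adjust(out$p_value)
  out
}

clinical_correlations <- function(pat) {
  rows <- list()
  for (col in c("illness_months", "education_years", "hdrs")) {
    if (!col %in% names(pat)) next
    res <- try_or_null(spearman_cor(pat, brain_pad, !!rlang::sym(col)))
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(covariate = col), res
    )
  }
  if (length(rows) == 0) return(NULL)
  dplyr::bind_rows(rows)
}

# Canonical machine-readable summary; numerics rounded to 8 significant
# digits so the serialization is byte-stable for identical runs.
summarize_run_json <- function(run) {
  cfg <- run$config
  cmp_list <- function(cmp) {
    if (is.null(cmp)) return(NULL)
    as.list(tidy(cmp))
  }
  payload <- list(
    config = list(
      mode = cfg$mode, harmonization = cfg$harmonization,
      learners = cfg$learners, k = cfg$k,
      holdout_fraction = cfg$holdout_fraction, seed = cfg$seed,
      synthetic = if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
    ),
    counts = as.list(run$split$counts),
    metrics = run$metrics,
    bias = as.list(tidy(run$bias)),
    comparison_corrected = cmp_list(run$comparison_corrected),
    comparison_uncorrected = cmp_list(run$comparison_uncorrected),
    glm_main = if (!is.null(run$glm_main)) tidy(run$glm_main),
    glm_clinical = if (!is.null(run$glm_clinical)) tidy(run$glm_clinical),
    subgroups = run$subgroups,
    correlations = run$correlations,
    importance_top20 = run$importance,
    edge_age = glance(run$edge_age),
    log = run$log
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  payload <- round_sig_df(payload, 8)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

# signif() on all numerics, descending into data frames and lists
round_sig_df <- function(x, digits) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) if (is.numeric(col)) signif(col, digits) else col)
    return(x)
  }
  if (is.list(x)) return(lapply(x, round_sig_df, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

#' @export
print.brainpad_run <- function(x, ...) {
  cat(sprintf("<brainpad_run> %s mode | harmonization: %s | seed %d\n",
              x$config$mode, x$config$harmonization, x$config$seed))
  cat(sprintf("  controls: %d train / %d hold-out; test subjects: %d\n",
              x$split$counts["train"], x$split$counts["holdout"],
              x$split$counts["test"]))
  stk <- x$metrics[x$metrics$model == "stacked" & x$metrics$set == "validation", ]
  if (nrow(stk) == 1) {
    cat(sprintf("  stacked validation MAE %.3f +/- %.3f years (R2 %.3f)\n",
                stk$mae, stk$mae_sd, stk$r2))
  }
  if (!is.null(x$comparison_corrected)) {
    cc <- x$comparison_corrected
    cat(sprintf("  corrected brain-PAD gap: %+.3f years (p = %.3g, d = %.3f)\n",
                cc$difference, cc$p_value, cc$cohens_d))
  }
  invisible(x)
}
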
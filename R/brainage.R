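#' Age-decile-stratified K-fold assignment
#'
#' Shuffled K-fold split, stratified by decile of the supplied ages so that
#' every fold covers the full age span. Deterministic under `seed`.
#'
#' @param ages Numeric vector of ages.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per subject.
#' @export
make_folds <- function(ages, k = 5, seed = 1L) {
  n <- length(ages)
  if (n < k) abort("fewer subjects than folds")
  strata <- age_decile(ages)
  fold <- integer(n)
  with_seed(as.integer(seed), {
    offset <- 0L
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across strata so fold sizes stay balanced
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Fit one base learner with five-fold out-of-fold predictions
#'
#' Trains `kind` on each of the K training folds (all subjects outside the
#' fold) and records, for every subject, the prediction made by the one
#' model that did not see them — the out-of-fold (OOF) prediction used
#' downstream by the stacking meta-learner.
#'
#' @param features Feature tibble (`subject_id` + edge columns).
#' @param ages Numeric vector of chronological ages, aligned with rows.
#' @param kind One of `"elastic_net"`, `"ridge"`, `"bayesian_ridge"`.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment.
#' @param params Pinned learner hyperparameters (see package vignette).
#' @return A list of class `base_fit`: `kind`, `fold` (assignment),
#'   `models` (per-fold coef/intercept), `train_ids` (per-fold training
#'   subject ids), `oof` (tibble subject_id, age, fold, oof_pred).
#' @export
fit_base <- function(features, ages, kind = "elastic_net", k = 5, seed = 1L,
                     params = list()) {
  x <- feature_matrix(features)
  if (length(ages) != nrow(x)) abort("ages not aligned with feature rows")
  if (anyNA(ages) || any(!is.finite(ages))) abort("ages must be finite")
  if (nrow(x) < 2 * k) abort(sprintf("need at least %d subjects for %d folds", 2 * k, k))
  if (sd(ages) == 0) abort("constant target: ages are all equal")
  kind <- match.arg(kind, learner_kinds())
  fold <- make_folds(ages, k = k, seed = seed)
  models <- vector("list", k)
  train_ids <- vector("list", k)
  oof <- rep(NA_real_, nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    models[[f]] <- fit_learner(x[tr, , drop = FALSE], ages[tr], kind, params)
    train_ids[[f]] <- rownames(x)[tr]
    oof[!tr] <- drop(x[!tr, , drop = FALSE] %*% models[[f]]$coef) +
      models[[f]]$intercept
  }
  structure(list(
    kind = kind, k = k, seed = as.integer(seed), fold = fold,
    models = models, train_ids = train_ids,
    edge_names = colnames(x),
    oof = tibble::tibble(subject_id = rownames(x), age = ages,
                         fold = fold, oof_pred = oof)
  ), class = "base_fit")
}

# Predict with one base_fit: average of the K per-fold models.
predict_base <- function(object, x) {
  preds <- vapply(object$models, function(m) {
    drop(x %*% m$coef) + m$intercept
  }, numeric(nrow(x)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# Per-fold predictions (n x k), for fold-wise Table-1-style metrics.
predict_base_folds <- function(object, x) {
  out <- vapply(object$models, function(m) {
    drop(x %*% m$coef) + m$intercept
  }, numeric(nrow(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' Fit the stacking meta-learner on out-of-fold predictions
#'
#' Ordinary least squares with intercept of age on the base learners'
#' out-of-fold prediction columns — the canonical linear stacking
#' combiner. Rank-deficient prediction matrices (e.g. two identical base
#' columns) are handled with the minimum-norm least-squares solution and a
#' warning.
#'
#' @param base_oof n x L matrix of out-of-fold predictions (one column per
#'   base learner).
#' @param ages Length-n vector of true ages.
#' @return List with `weights` (length L), `intercept`, `learners` (column
#'   names).
#' @export
fit_stacking <- function(base_oof, ages) {
  x <- as.matrix(base_oof)
  if (anyNA(x)) abort("out-of-fold prediction matrix contains missing values")
  if (nrow(x) != length(ages)) abort("ages not aligned with predictions")
  xd <- cbind(intercept = 1, x)
  sv <- svd(xd)
  pos <- sv$d > max(sv$d) * 1e-10
  if (sum(pos) < ncol(xd)) {
    warn("rank-deficient base predictions; using minimum-norm least squares")
  }
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- drop(sv$v %*% (dinv * crossprod(sv$u, ages)))
  list(weights = setNames(beta[-1], colnames(x)), intercept = beta[1],
       learners = colnames(x))
}

#' Fit the full stacked brain-age model
#'
#' Fits every requested base learner with K-fold out-of-fold discipline
#' ([fit_base()]) and combines them with an OLS stacking meta-learner
#' fitted only on the out-of-fold predictions ([fit_stacking()]).
#'
#' @inheritParams fit_base
#' @param learners Character vector of base learner kinds.
#' @return A list of class `brainage_model`: `base` (named list of
#'   `base_fit`s), `meta` (stacking weights), `oof` (tibble with per-learner
#'   OOF columns and `stacked` OOF prediction), `k`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_controls = 60, n_patients = 1, n_sites = 2, n_regions = 6,
#'   edge_slope_sd = 0.02, subject_sd = 2, seed = 3
#' ))
#' ctrl <- cohort$phenotypes$group == "control"
#' model <- fit_brainage(cohort$features[ctrl, ], cohort$phenotypes$age[ctrl])
#' glance(model)
fit_brainage <- function(features, ages, learners = learner_kinds(),
                         k = 5, seed = 1L, params = list()) {
  learners <- match.arg(learners, learner_kinds(), several.ok = TRUE)
  base <- lapply(learners, function(kind) {
    fit_base(features, ages, kind = kind, k = k, seed = seed, params = params)
  })
  names(base) <- learners
  oof_mat <- vapply(base, function(b) b$oof$oof_pred, numeric(length(ages)))
  colnames(oof_mat) <- learners
  meta <- fit_stacking(oof_mat, ages)
  stacked_oof <- drop(oof_mat %*% meta$weights) + meta$intercept
  oof <- dplyr::bind_cols(
    tibble::tibble(subject_id = base[[1]]$oof$subject_id, age = ages,
                   fold = base[[1]]$fold),
    tibble::as_tibble(oof_mat), tibble::tibble(stacked = stacked_oof)
  )
  structure(list(base = base, meta = meta, oof = oof, k = k,
                 seed = as.integer(seed), learners = learners,
                 edge_names = base[[1]]$edge_names),
            class = "brainage_model")
}

#' Predict ages with a fitted brain-age model
#'
#' Base predictions for new subjects average the K per-fold models of each
#' learner; the stacking weights are then applied. `per_fold = TRUE`
#' instead returns one stacked prediction per fold model (columns), which
#' is how fold-wise test metrics (mean +/- SD across folds) are computed.
#'
#' @param object A `brainage_model`.
#' @param features Feature tibble for the new subjects.
#' @param type `"stacked"` (default) or one of the base learner kinds.
#' @param per_fold Return an n x K matrix of per-fold predictions.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (or matrix if `per_fold`).
#' @export
predict.brainage_model <- function(object, features, type = "stacked",
                                   per_fold = FALSE, ...) {
  x <- feature_matrix(features)
  if (!identical(colnames(x), object$edge_names)) {
    if (!setequal(colnames(x), object$edge_names)) {
      abort("feature columns do not match the trained model")
    }
    x <- x[, object$edge_names, drop = FALSE]
  }
  if (type != "stacked") {
    type <- match.arg(type, object$learners)
    if (per_fold) return(predict_base_folds(object$base[[type]], x))
    return(predict_base(object$base[[type]], x))
  }
  if (per_fold) {
    per <- lapply(object$base, function(b) predict_base_folds(b, x))
    out <- matrix(object$meta$intercept, nrow(x), object$k)
    for (l in object$learners) {
      out <- out + object$meta$weights[[l]] * per[[l]]
    }
    rownames(out) <- rownames(x)
    return(out)
  }
  base_pred <- vapply(object$base, function(b) predict_base(b, x),
                      numeric(nrow(x)))
  if (is.null(dim(base_pred))) base_pred <- matrix(base_pred, nrow = 1)
  drop(base_pred %*% object$meta$weights) + object$meta$intercept
}

#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf("<brainage_model> learners: %s | %d-fold | n = %d\n",
              paste(x$learners, collapse = ", "), x$k, nrow(x$oof)))
  w <- x$meta$weights
  cat("stacking weights:", paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
      sprintf("(intercept %.3f)\n", x$meta$intercept))
  invisible(x)
}

#' Prediction accuracy metrics
#'
#' Mean absolute error (years), mean squared error (years squared) and the
#' coefficient of determination R-squared = 1 - SS_res / SS_tot.
#'
#' @param pred,truth Equal-length numeric vectors (n >= 2).
#' @return One-row tibble with `mae`, `mse`, `r2`.
#' @export
#' @examples
#' evaluate(c(20, 30), c(25, 25))
evaluate <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth differ in length")
  if (length(pred) < 2) abort("need at least 2 observations")
  err <- pred - truth
  ss_tot <- sum((truth - mean(truth))^2)
  tibble::tibble(
    mae = mean(abs(err)),
    mse = mean(err^2),
    r2 = 1 - sum(err^2) / ss_tot
  )
}

#' Normalized feature importance of a fitted model
#'
#' Importance of each edge is the absolute coefficient averaged over the K
#' fold models, normalized to sum to one. For a stacked model the
#' per-learner importances are combined with weights proportional to the
#' absolute stacking weights. Ranking ties are broken by edge index.
#'
#' @param model A `brainage_model` or `base_fit`.
#' @param learner For a stacked model, restrict to one base learner.
#' @param top_n Optionally return only the top edges.
#' @return Tibble `edge`, `importance`, `rank`, sorted by rank.
#' @export
feature_importance <- function(model, learner = NULL, top_n = NULL) {
  if (inherits(model, "base_fit")) {
    imp <- base_importance(model)
    edges <- model$edge_names
  } else if (inherits(model, "brainage_model")) {
    edges <- model$edge_names
    if (!is.null(learner)) {
      learner <- match.arg(learner, model$learners)
      imp <- base_importance(model$base[[learner]])
    } else {
      w <- abs(model$meta$weights)
      if (sum(w) == 0) w[] <- 1
      w <- w / sum(w)
      per <- vapply(model$learners, function(l) base_importance(model$base[[l]]),
                    numeric(length(edges)))
      imp <- drop(per %*% w)
    }
  } else {
    abort("not a fitted brain-age model")
  }
  total <- sum(imp)
  imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  ord <- order(-imp, seq_along(imp))
  out <- tibble::tibble(edge = edges, importance = imp)[ord, ]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

base_importance <- function(b) {
  cf <- vapply(b$models, function(m) abs(m$coef), numeric(length(b$edge_names)))
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  rowMeans(cf)
}

#' Edgewise correlations between connectivity and age
#'
#' Pearson correlation of every edge with chronological age, with the
#' signed-count summary used to characterize the aging connectome: how many
#' edges strengthen vs weaken with age, mean +/- SD within each sign group,
#' and the extreme edges. Constant edges are recorded as correlation 0 with
#' a flag.
#'
#' @param features Feature tibble.
#' @param ages Aligned numeric ages (n >= 3).
#' @return A list of class `edge_age_cor`: `edges` (tibble edge, r,
#'   constant flag) and `summary` (counts, group means/SDs, extremes).
#' @export
edge_age_correlations <- function(features, ages) {
  x <- feature_matrix(features)
  if (length(ages) != nrow(x)) abort("ages not aligned with feature rows")
  if (nrow(x) < 3) abort("need at least 3 subjects")
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  r <- rep(0, ncol(x))
  ok <- !constant
  if (any(ok)) {
    r[ok] <- drop(cor(x[, ok, drop = FALSE], ages))
  }
  edges <- tibble::tibble(edge = colnames(x), r = r, constant = constant)
  pos <- r > 0 & !constant
  neg <- r < 0 & !constant
  summary <- list(
    n_edges = ncol(x),
    n_positive = sum(pos), n_negative = sum(neg),
    n_zero = sum(!pos & !neg),
    mean_positive = if (any(pos)) mean(r[pos]) else NA_real_,
    sd_positive = if (sum(pos) > 1) sd(r[pos]) else NA_real_,
    mean_negative = if (any(neg)) mean(r[neg]) else NA_real_,
    sd_negative = if (sum(neg) > 1) sd(r[neg]) else NA_real_,
    max_edge = edges$edge[which.max(r)], max_r = max(r),
    min_edge = edges$edge[which.min(r)], min_r = min(r)
  )
  structure(list(edges = edges, summary = summary), class = "edge_age_cor")
}

#' @export
print.edge_age_cor <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<edge_age_cor> %d edges: %d positive, %d negative, %d zero-flagged\n",
              s$n_edges, s$n_positive, s$n_negative, s$n_zero))
  cat(sprintf("  max r = %.4f (%s), min r = %.4f (%s)\n",
              s$max_r, s$max_edge, s$min_r, s$min_edge))
  invisible(x)
}

# Fold-wise Table-1-style metrics for every model on a given set.
metrics_by_fold <- function(model, features, ages, set_label) {
  rows <- list()
  for (l in c(model$learners, "stacked")) {
    per <- predict.brainage_model(model, features,
                                  type = if (l == "stacked") "stacked" else l,
                                  per_fold = TRUE)
    m <- do.call(rbind, lapply(seq_len(ncol(per)), function(f) {
      evaluate(per[, f], ages)
    }))
    rows[[l]] <- tibble::tibble(
      model = l, set = set_label,
      mae = mean(m$mae), mae_sd = sd(m$mae),
      mse = mean(m$mse), mse_sd = sd(m$mse),
      r2 = mean(m$r2), r2_sd = sd(m$r2)
    )
  }
  dplyr::bind_rows(rows)
}
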
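#' Split controls into training and hold-out sets
#'
#' Hold-out controls are drawn from every site across the entire age span:
#' the hold-out count per site is allocated by largest remainder around
#' `holdout_fraction` (so the global hold-out size is exactly
#' `round(holdout_fraction * n_controls)` up to the site-minimum
#' constraints), and within each site subjects are taken by systematic
#' sampling along the age ordering with a random phase, which stratifies by
#' age. Every site with at least 2 controls contributes to both subsets; a
#' site with a single control goes to training with a warning. Patients are
#' never in a control subset — they form the test set.
#'
#' @param phenotypes Phenotype tibble with `subject_id`, `site`, `age`,
#'   `group` (`"control"` vs anything else = patient).
#' @param holdout_fraction Fraction of controls held out, in (0, 0.5].
#' @param seed Integer seed.
#' @return A list of class `cohort_split`: `train_ids`, `holdout_ids`,
#'   `test_ids`, `counts`.
#' @export
make_split <- function(phenotypes, holdout_fraction = 0.2, seed = 1L) {
  stopifnot(all(c("subject_id", "site", "age", "group") %in% names(phenotypes)))
  if (holdout_fraction <= 0 || holdout_fraction > 0.5) {
    abort("holdout_fraction must lie in (0, 0.5]")
  }
  ph <- phenotypes
  is_ctrl <- ph$group == "control"
  if (!any(is_ctrl)) abort("no controls present")
  ctrl <- ph[is_ctrl, ]
  sites <- split(seq_len(nrow(ctrl)), as.character(ctrl$site))
  n_ctrl <- nrow(ctrl)
  target <- round(holdout_fraction * n_ctrl)
  sizes <- vapply(sites, length, integer(1))
  singletons <- names(sites)[sizes == 1]
  if (length(singletons) > 0) {
    warn(paste0("site(s) with a single control assigned to training: ",
                paste(singletons, collapse = ", ")))
  }
  eligible <- names(sites)[sizes >= 2]
  # largest-remainder allocation with per-site bounds [1, n_s - 1]
  quota <- holdout_fraction * sizes[eligible]
  alloc <- pmin(pmax(floor(quota), 1L), sizes[eligible] - 1L)
  total_target <- min(max(target, length(eligible)),
                      sum(sizes[eligible] - 1L))
  rem <- quota - floor(quota)
  ord <- order(-rem)
  i <- 1L
  while (sum(alloc) < total_target && i <= 10 * length(eligible)) {
    s <- eligible[ord[((i - 1L) %% length(eligible)) + 1L]]
    if (alloc[s] < sizes[s] - 1L) alloc[s] <- alloc[s] + 1L
    i <- i + 1L
  }
  while (sum(alloc) > total_target) {
    ord2 <- order(rem)
    moved <- FALSE
    for (s in eligible[ord2]) {
      if (alloc[s] > 1L) { alloc[s] <- alloc[s] - 1L; moved <- TRUE; break }
    }
    if (!moved) break
  }
  holdout_idx <- integer(0)
  with_seed(as.integer(seed), {
    for (s in eligible) {
      idx <- sites[[s]]
      idx <- idx[order(ctrl$age[idx])]
      m <- alloc[[s]]
      # systematic sampling along the age ordering with random phase
      step <- length(idx) / m
      phase <- runif(1, 0, step)
      pick <- unique(pmin(length(idx), ceiling(phase + step * (seq_len(m) - 1))))
      while (length(pick) < m) {
        extra <- setdiff(seq_along(idx), pick)
        pick <- c(pick, extra[sample.int(length(extra), 1)])
      }
      holdout_idx <- c(holdout_idx, idx[pick])
    }
  })
  holdout_ids <- ctrl$subject_id[sort(holdout_idx)]
  train_ids <- setdiff(ctrl$subject_id, holdout_ids)
  test_ids <- ph$subject_id[!is_ctrl]
  structure(list(
    train_ids = train_ids, holdout_ids = holdout_ids, test_ids = test_ids,
    holdout_fraction = holdout_fraction, seed = as.integer(seed),
    counts = c(train = length(train_ids), holdout = length(holdout_ids),
               test = length(test_ids))
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d training controls / %d hold-out controls / %d test subjects\n",
              x$counts["train"], x$counts["holdout"], x$counts["test"]))
  invisible(x)
}

#' Fit the age-bias correction on hold-out controls
#'
#' Least-squares regression of raw predicted age on chronological age in
#' the hold-out control set: `predicted = slope * age + intercept`. The
#' slope and intercept are then used by [apply_bias()] to rescale raw
#' predictions, removing the regression-to-the-mean bias of brain-age
#' estimators.
#'
#' @param holdout_pred Raw predicted ages of hold-out controls.
#' @param holdout_age Their chronological ages (n >= 3, not all equal).
#' @return A list of class `bias_corrector`: `slope`, `intercept`, `n`,
#'   `residual_sd`.
#' @export
fit_bias <- function(holdout_pred, holdout_age) {
  if (length(holdout_pred) != length(holdout_age)) abort("length mismatch")
  if (length(holdout_age) < 3) abort("need at least 3 hold-out controls")
  if (sd(holdout_age) == 0) abort("hold-out ages are all equal")
  fit <- lm(holdout_pred ~ holdout_age)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (abs(slope) < 1e-6) {
    abort("fitted slope is ~0: predictions carry no age information; correction undefined")
  }
  structure(list(slope = slope, intercept = intercept,
                 n = length(holdout_age),
                 residual_sd = sd(fit$residuals)),
            class = "bias_corrector")
}

#' @export
print.bias_corrector <- function(x, ...) {
  cat(sprintf("<bias_corrector> corrected = (pred - %.4f) / %.4f  [n = %d, residual SD %.2f]\n",
              x$intercept, x$slope, x$n, x$residual_sd))
  invisible(x)
}

#' Apply the age-bias correction and compute brain-PAD
#'
#' Corrected predicted age is `(raw - intercept) / slope`; brain-PAD is
#' corrected predicted age minus chronological age (exact identity). On the
#' hold-out set the correction was fitted on, brain-PAD is uncorrelated
#' with age by least-squares orthogonality.
#'
#' @param corrector A [fit_bias()] result.
#' @param data Tibble with at least `subject_id` and `age`; a `raw_pred`
#'   column, or supply `pred`.
#' @param pred Optional numeric vector of raw predicted ages, aligned with
#'   `data` rows.
#' @return Tibble: the input columns plus `raw_pred`, `corrected_pred`,
#'   `brain_pad`.
#' @export
apply_bias <- function(corrector, data, pred = NULL) {
  if (!inherits(corrector, "bias_corrector")) abort("not a fitted bias_corrector")
  stopifnot(is.data.frame(data), "age" %in% names(data))
  if (is.null(pred)) {
    if (!"raw_pred" %in% names(data)) abort("supply pred or a raw_pred column")
    pred <- data$raw_pred
  }
  if (length(pred) != nrow(data)) abort("pred not aligned with data rows")
  corrected <- (pred - corrector$intercept) / corrector$slope
  out <- data
  out$raw_pred <- pred
  out$corrected_pred <- corrected
  out$brain_pad <- corrected - out$age
  tibble::as_tibble(out)
}
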
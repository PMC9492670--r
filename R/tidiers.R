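# broom-style tidy()/glance() methods for the fitted objects.

#' @describeIn fit_brainage Tidy the stacking weights and base-learner
#'   out-of-fold MAEs.
#' @param x A `brainage_model`.
#' @param ... Unused.
#' @export
tidy.brainage_model <- function(x, ...) {
  oof <- x$oof
  purrr::map_dfr(c(x$learners, "stacked"), function(l) {
    m <- evaluate(oof[[l]], oof$age)
    tibble::tibble(
      learner = l,
      weight = if (l == "stacked") NA_real_ else unname(x$meta$weights[[l]]),
      oof_mae = m$mae, oof_mse = m$mse, oof_r2 = m$r2
    )
  })
}

#' @describeIn fit_brainage One-row out-of-fold summary of the stacked
#'   model.
#' @export
glance.brainage_model <- function(x, ...) {
  m <- evaluate(x$oof$stacked, x$oof$age)
  tibble::tibble(n = nrow(x$oof), k = x$k,
                 mae = m$mae, mse = m$mse, r2 = m$r2)
}

#' @describeIn glm_brainpad Coefficient table as a tibble.
#' @param x A `brainpad_glm`.
#' @param ... Unused.
#' @export
tidy.brainpad_glm <- function(x, ...) x$coefficients

#' @describeIn glm_brainpad One-row model summary.
#' @export
glance.brainpad_glm <- function(x, ...) {
  tibble::tibble(n = x$n_used, n_dropped = x$n_dropped,
                 df_residual = x$fit$df.residual,
                 deviance = x$fit$deviance)
}

#' @describeIn compare_groups One-row tidy comparison.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$groups[1], group_b = x$groups[2],
    n_a = x$n[1], n_b = x$n[2],
    mean_a = x$means[1], mean_b = x$means[2],
    sd_a = x$sds[1], sd_b = x$sds[2],
    difference = x$difference, t = x$t, df = x$df,
    p_value = x$p_value, cohens_d = x$cohens_d,
    conf_low = x$conf_low, conf_high = x$conf_high
  )
}

#' @describeIn fit_bias Slope/intercept as a one-row tibble.
#' @param x A `bias_corrector`.
#' @param ... Unused.
#' @export
tidy.bias_corrector <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n = x$n, residual_sd = x$residual_sd)
}

#' @describeIn edge_age_correlations Per-edge correlation tibble.
#' @param x An `edge_age_cor`.
#' @param ... Unused.
#' @export
tidy.edge_age_cor <- function(x, ...) x$edges

#' @describeIn edge_age_correlations Signed-count summary as one row.
#' @export
glance.edge_age_cor <- function(x, ...) {
  tibble::as_tibble(x$summary)
}
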
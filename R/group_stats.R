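#' Two-group brain-PAD comparison
#'
#' Welch two-sample t-test (default; Student's pooled-variance test behind
#' `var_equal = TRUE`), Cohen's d with pooled SD (optional Hedges
#' correction), and the 95% confidence interval of the mean difference.
#' The difference and d are oriented as `group b - group a`, where b is the
#' second factor level (e.g. patients minus controls).
#'
#' @param data Data frame holding the outcome and grouping columns.
#' @param pad Column with the outcome (default `brain_pad`), tidy-eval.
#' @param group Grouping column (exactly 2 levels), tidy-eval.
#' @param conf_level Confidence level (default 0.95).
#' @param var_equal Use the pooled-variance Student test.
#' @param hedges Apply the small-sample Hedges correction to d.
#' @return A list of class `group_comparison` with group labels, per-group
#'   n / mean / SD, `difference`, `t`, `df`, `p_value`, `cohens_d`,
#'   `conf_low`, `conf_high`.
#' @export
#' @examples
#' d <- data.frame(pad = c(1, 2, 3, 3, 4, 5), g = rep(c("a", "b"), each = 3))
#' compare_groups(d, pad, g)
compare_groups <- function(data, pad = brain_pad, group = group,
                           conf_level = 0.95, var_equal = FALSE,
                           hedges = FALSE) {
  y <- dplyr::pull(data, {{ pad }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) abort("grouping column must have exactly 2 levels")
  ya <- y[g == levels(g)[1]]
  yb <- y[g == levels(g)[2]]
  if (length(ya) < 2 || length(yb) < 2) abort("each group needs n >= 2")
  s1 <- sd(ya); s2 <- sd(yb)
  if (s1 == 0 && s2 == 0 && mean(ya) == mean(yb)) {
    abort("both groups constant and equal: effect size undefined")
  }
  n1 <- length(ya); n2 <- length(yb)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  diff <- mean(yb) - mean(ya)
  d <- if (sp > 0) diff / sp else sign(diff) * Inf
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  tt <- t.test(yb, ya, var.equal = var_equal, conf.level = conf_level)
  structure(list(
    groups = levels(g),
    n = c(n1, n2), means = c(mean(ya), mean(yb)), sds = c(s1, s2),
    difference = diff,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, cohens_d = d,
    conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
    conf_level = conf_level, var_equal = var_equal
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d, mean %.3f, SD %.3f) vs %s (n=%d, mean %.3f, SD %.3f)\n",
    x$groups[1], x$n[1], x$means[1], x$sds[1],
    x$groups[2], x$n[2], x$means[2], x$sds[2]
  ))
  cat(sprintf("  difference %+.3f years [%.0f%% CI %.3f, %.3f], t = %.3f, p = %.3g, Cohen's d = %.3f\n",
              x$difference, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$t, x$p_value, x$cohens_d))
  invisible(x)
}

#' Gaussian GLM for brain-PAD against covariates
#'
#' Fits a Gaussian-family identity-link GLM of brain-PAD on the requested
#' terms and reports the coefficient table in the conventional layout:
#' estimate, SE, Wald z, normal-approximation p, and the `conf_level`
#' Wald confidence bounds. The term `"age2"` is computed internally as the
#' square of the (by default uncentered) `age` column. Rows with missing
#' values in any requested term are dropped, with the count recorded.
#'
#' @param data Data frame with a `brain_pad` column and the covariates.
#' @param terms Character vector of covariate names (e.g.
#'   `c("sex", "group", "age", "age2")`).
#' @param response Name of the outcome column (default `"brain_pad"`).
#' @param center_age Center age before squaring (default `FALSE`).
#' @param conf_level Confidence level for the Wald bounds.
#' @return A list of class `brainpad_glm`: `coefficients` (tibble), `fit`
#'   (the `glm` object), `n_used`, `n_dropped`.
#' @export
glm_brainpad <- function(data, terms = c("sex", "group", "age", "age2"),
                         response = "brain_pad", center_age = FALSE,
                         conf_level = 0.95) {
  stopifnot(is.data.frame(data), response %in% names(data))
  base_terms <- setdiff(terms, c("age2", "1")) # "1" = intercept-only
  missing_terms <- setdiff(base_terms, names(data))
  if (length(missing_terms) > 0) {
    abort(paste0("terms not found in data: ", paste(missing_terms, collapse = ", ")))
  }
  df <- data[, c(response, base_terms), drop = FALSE]
  cc <- complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if ("age2" %in% terms) {
    if (!"age" %in% names(df)) abort("age2 requested but no age column")
    a <- if (center_age) df$age - mean(df$age) else df$age
    df$age2 <- a^2
  }
  if (nrow(df) <= length(terms) + 1) abort("too few complete cases for the requested terms")
  for (tm in setdiff(terms, "1")) {
    v <- df[[tm]]
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("singular design: term '%s' is constant", tm))
    }
  }
  form <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- glm(form, data = df, family = gaussian())
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("singular design: aliased term(s) ", paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  est <- unname(sm[, 1]); se <- unname(sm[, 2])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = est, std_error = se,
    z = est / se,
    p_value = 2 * pnorm(-abs(est / se)),
    conf_low = est - zq * se,
    conf_high = est + zq * se
  )
  structure(list(coefficients = coefs, fit = fit,
                 n_used = nrow(df), n_dropped = n_dropped,
                 terms = terms, conf_level = conf_level),
            class = "brainpad_glm")
}

#' @export
print.brainpad_glm <- function(x, ...) {
  cat(sprintf("<brainpad_glm> n = %d (%d dropped for missingness)\n",
              x$n_used, x$n_dropped))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), via
#' `stats::p.adjust(method = "BH")` after input validation.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation with two-sided p
#'
#' Rank correlation using average ranks for ties; the two-sided p-value
#' uses the t approximation (appropriate with ties).
#'
#' @param data Data frame.
#' @param x,y Columns to correlate, tidy-eval.
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_cor(data.frame(a = 1:5, b = c(2, 1, 4, 3, 5)), a, b)
spearman_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("constant variable: rank correlation undefined")
  rho <- cor(rank(xv), rank(yv))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Median split of a continuous covariate
#'
#' Partitions subjects into `below` (value < median) and `at_or_above`
#' (value >= median); the boundary goes to the upper group, matching the
#' "fewer than m" vs "greater than or equal to m" convention.
#'
#' @param data Data frame.
#' @param col Covariate column, tidy-eval. Missing values are dropped.
#' @param threshold Optional explicit threshold; defaults to the median of
#'   the non-missing values.
#' @return The input rows with non-missing covariate plus a `subgroup`
#'   factor column; the threshold and group sizes are attached as
#'   attributes `threshold` and `sizes`.
#' @export
#' @examples
#' median_split(data.frame(x = c(10, 12, 14)), x)
median_split <- function(data, col, threshold = NULL) {
  v <- dplyr::pull(data, {{ col }})
  keep <- !is.na(v)
  out <- data[keep, , drop = FALSE]
  v <- v[keep]
  if (length(unique(v)) < 2) abort("covariate has < 2 distinct values")
  thr <- threshold %||% median(v)
  out$subgroup <- factor(ifelse(v < thr, "below", "at_or_above"),
                         levels = c("below", "at_or_above"))
  if (any(table(out$subgroup) == 0)) {
    abort("median split produced an empty subgroup")
  }
  out <- tibble::as_tibble(out)
  attr(out, "threshold") <- thr
  attr(out, "sizes") <- as.integer(table(out$subgroup))
  out
}
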
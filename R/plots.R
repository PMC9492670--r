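# ggplot2 figures for the main result types.

#' Predicted vs chronological age scatter
#'
#' @param predictions Tibble with `age`, a prediction column and optionally
#'   `group`.
#' @param pred Prediction column (default `corrected_pred`), tidy-eval.
#' @return A ggplot object.
#' @export
plot_age_scatter <- function(predictions, pred = corrected_pred) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$age, y = {{ pred }}))
  if ("group" %in% names(predictions)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE, linewidth = 0.6) +
    ggplot2::labs(x = "chronological age (years)", y = "predicted age (years)")
}

#' Brain-PAD by group
#'
#' Box + jitter panel of brain-PAD scores per group, the usual display for
#' accelerated-aging group comparisons.
#'
#' @param predictions Tibble with `brain_pad` and a grouping column.
#' @param group Grouping column (default `group`), tidy-eval.
#' @return A ggplot object.
#' @export
plot_pad_groups <- function(predictions, group = group) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = {{ group }}, y = .data$brain_pad,
                               fill = {{ group }})) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "brain-PAD (years)") +
    ggplot2::guides(fill = "none")
}

#' Top edges by feature importance
#'
#' @param importance Tibble from [feature_importance()].
#' @param top_n Number of edges to show (default 20).
#' @return A ggplot object.
#' @export
plot_top_edges <- function(importance, top_n = 20) {
  df <- head(dplyr::arrange(importance, .data$rank), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$edge, .data$importance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalized importance", y = NULL)
}

#' @describeIn edge_age_correlations Histogram of edgewise age
#'   correlations, split by sign.
#' @param object An `edge_age_cor`.
#' @param ... Unused.
#' @export
autoplot.edge_age_cor <- function(object, ...) {
  df <- object$edges
  df$sign <- factor(ifelse(df$r > 0, "positive", "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, fill = .data$sign)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "edge-age Pearson correlation", y = "edges") +
    ggplot2::guides(fill = "none")
}

#' @describeIn run_pipeline Default figure for a pipeline run: predicted
#'   age scatter (`which = "age"`), brain-PAD by group (`"pad"`), or top
#'   feature importances (`"importance"`).
#' @param object A `brainpad_run`.
#' @param which One of `"age"`, `"pad"`, `"importance"`.
#' @param ... Unused.
#' @export
autoplot.brainpad_run <- function(object, which = c("age", "pad", "importance"),
                                  ...) {
  which <- match.arg(which)
  switch(which,
    age = plot_age_scatter(object$predictions),
    pad = plot_pad_groups(object$predictions),
    importance = plot_top_edges(object$importance)
  )
}
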
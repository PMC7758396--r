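#' Plot an ROC curve
#'
#' Staircase ROC plot with the chance diagonal and an AUC annotation.
#'
#' @param object A [roc_curve()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' profiles <- simulate_profiles(sim_config(seed = 1))
#' model <- fit_panel_model(profiles)
#' autoplot(roc_curve(score_panel(model, profiles)))
#' @method autoplot panel_roc
#' @export
autoplot.panel_roc <- function(object, ...) {
  lab <- sprintf(
    "AUC %.3f (95%% CI %.3f–%.3f)",
    object$auc, object$auc_ci[["upper"]], object$auc_ci[["lower"]]
  )
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(
      intercept = 0, slope = 1, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::annotate(
      "text", x = 0.65, y = 0.1, label = lab, size = 3.4, hjust = 0.5
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC — positive class: %s", object$positive)
    ) +
    ggplot2::theme_minimal()
}

#' Plot confusion-summary metrics with their Wald intervals
#'
#' @param object A [confusion_summary()] object.
#' @param ... Unused.
#' @return A ggplot object. The dashed lines mark 0 and 100%; unclipped
#'   Wald bounds may extend beyond them.
#' @method autoplot confusion_summary
#' @export
autoplot.confusion_summary <- function(object, ...) {
  m <- object$metrics
  m$metric <- factor(
    m$metric,
    levels = c("sensitivity", "specificity", "ppv", "npv")
  )
  ggplot2::ggplot(
    m,
    ggplot2::aes(x = .data$metric, y = .data$estimate)
  ) +
    ggplot2::geom_hline(
      yintercept = c(0, 100), linetype = "dashed", colour = "grey70"
    ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      colour = "#2c7fb8"
    ) +
    ggplot2::labs(
      x = NULL, y = "Percent (95% Wald CI, unclipped)",
      title = sprintf("Diagnostic performance — positive: %s", object$positive)
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of D Scores by true label
#'
#' The classifier-facing analogue of per-gene expression box plots: the
#' distribution of the D Score in each truth group, with the D = 0 decision
#' boundary marked.
#'
#' @param scores Output of [score_panel()] including a `label` column.
#' @return A ggplot object.
#' @export
plot_d_score <- function(scores) {
  if (!all(c("label", "d_score") %in% names(scores))) {
    rlang::abort("`scores` must contain `label` and `d_score` columns.")
  }
  ggplot2::ggplot(
    scores,
    ggplot2::aes(x = .data$label, y = .data$d_score, fill = .data$label)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_boxplot(alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "D Score",
      title = "D Score by pathology group (boundary at 0)"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-gene group mean differences
#'
#' @param gene_tests Output of [gene_ttests()].
#' @return A ggplot object; significant genes are filled darker.
#' @export
plot_gene_differences <- function(gene_tests) {
  gt <- gene_tests
  gt$gene <- stats::reorder(gt$gene, gt$difference)
  ggplot2::ggplot(
    gt,
    ggplot2::aes(x = .data$gene, y = .data$difference, fill = .data$significant)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
      name = "p < 0.05"
    ) +
    ggplot2::labs(
      x = NULL, y = "Group mean difference (CtS scale)",
      title = "Per-gene differential expression"
    ) +
    ggplot2::theme_minimal()
}
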
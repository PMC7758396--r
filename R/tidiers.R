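#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the coefficients of a panel model
#'
#' Returns the fitted score polynomial in long form: one row per class and
#' term, where terms are `(constant)`, each gene (linear coefficients), and
#' each gene pair `"A:B"` (quadratic coefficients; off-diagonal pairs are
#' reported once with the coefficient for `x_i x_j + x_j x_i` combined, as
#' the printed polynomial writes them).
#'
#' @param x A [fit_panel_model()] object.
#' @param ... Unused.
#' @return Tibble with columns `class`, `role` (positive/negative), `term`,
#'   `estimate`.
#' @method tidy panel_model
#' @export
tidy.panel_model <- function(x, ...) {
  genes <- x$panel
  p <- length(genes)
  purrr::map(names(x$constant), function(cl) {
    role <- names(x$classes)[x$classes == cl]
    Q <- x$quad[[cl]]
    ut <- which(upper.tri(Q, diag = TRUE), arr.ind = TRUE)
    # combined coefficient of the monomial x_i x_j (j >= i)
    qcoef <- ifelse(ut[, 1] == ut[, 2], diag(Q)[ut[, 1]],
      2 * Q[ut]
    )
    tibble::tibble(
      class = cl,
      role = role,
      term = c(
        "(constant)", genes,
        paste0(genes[ut[, 1]], ":", genes[ut[, 2]])
      ),
      estimate = c(x$constant[[cl]], x$linear[, cl], qcoef)
    )
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a panel model
#'
#' @param x A [fit_panel_model()] object.
#' @param ... Unused.
#' @return Tibble with sample sizes, panel size, priors, shrinkage and the
#'   log-determinants of the class covariances.
#' @method glance panel_model
#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n = sum(x$n_per_class),
    n_positive = x$n_per_class[[1]],
    n_negative = x$n_per_class[[2]],
    n_genes = length(x$panel),
    prior_positive = x$priors[[1]],
    prior_mode = x$prior_mode,
    shrinkage = x$shrinkage,
    log_det_positive = x$log_det[[1]],
    log_det_negative = x$log_det[[2]]
  )
}

#' Tidy a confusion summary
#'
#' @param x A [confusion_summary()] object.
#' @param ... Unused.
#' @return Tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `conf.low`, `conf.high` (percent, Wald,
#'   unclipped).
#' @method tidy confusion_summary
#' @export
tidy.confusion_summary <- function(x, ...) {
  x$metrics
}

#' One-row summary of a confusion summary
#'
#' @param x A [confusion_summary()] object.
#' @param ... Unused.
#' @return Tibble with the 2x2 counts, accuracy and prevalence (percent).
#' @method glance confusion_summary
#' @export
glance.confusion_summary <- function(x, ...) {
  n <- x$tp + x$fp + x$fn + x$tn
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = n,
    accuracy = 100 * (x$tp + x$tn) / n,
    prevalence = 100 * (x$tp + x$fn) / n,
    positive = x$positive
  )
}

#' Tidy an ROC curve
#'
#' @param x A [roc_curve()] object.
#' @param ... Unused.
#' @return The `(threshold, fpr, tpr)` point table.
#' @method tidy panel_roc
#' @export
tidy.panel_roc <- function(x, ...) {
  x$points
}

#' One-row summary of an ROC curve
#'
#' @param x A [roc_curve()] object.
#' @param ... Unused.
#' @return Tibble with `auc`, its standard error and 95% interval, and the
#'   group sizes.
#' @method glance panel_roc
#' @export
glance.panel_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_se = x$auc_se,
    conf.low = x$auc_ci[["lower"]], conf.high = x$auc_ci[["upper"]],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}
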
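#' Unclipped Wald interval for a binomial proportion
#'
#' Normal-approximation interval \eqn{\hat p \pm z \sqrt{\hat p (1 - \hat p)
#' / n}}, reported in percent and deliberately NOT clipped to \[0, 100\]:
#' diagnostic-performance tables in this field print bounds above 100% for
#' near-perfect metrics, and the unclipped form is what reproduces them.
#'
#' @param k Successes (vectorized).
#' @param n Trials (vectorized).
#' @param z Normal quantile, default 1.96 (95%).
#' @return Tibble with `estimate`, `conf.low`, `conf.high`, all in percent,
#'   plus the input `k` and `n`.
#' @examples
#' wald_interval(51, 52) # 98.08 (94.34, 101.81)
#' @export
wald_interval <- function(k, n, z = 1.96) {
  if (length(n) == 1L) n <- rep(n, length(k))
  if (length(k) != length(n)) {
    rlang::abort("`k` and `n` must have the same length.")
  }
  if (any(n < 1)) rlang::abort("`n` must be at least 1.")
  if (any(k < 0 | k > n)) rlang::abort("Need 0 <= k <= n.")
  p <- k / n
  hw <- z * sqrt(p * (1 - p) / n)
  tibble::tibble(
    k = k, n = n,
    estimate = 100 * p,
    conf.low = 100 * (p - hw),
    conf.high = 100 * (p + hw)
  )
}

#' Confusion summary with Wald intervals
#'
#' Cross-tabulates predicted against true binary labels and computes
#' sensitivity, specificity, PPV and NPV, each with an unclipped 95% Wald
#' interval (see [wald_interval()]). Samples whose truth or call is `NA` or
#' `"unknown"` are dropped with a message.
#'
#' @param data Tibble holding the call and truth columns (e.g. the output of
#'   [score_panel()]).
#' @param truth Unquoted column of true labels (default `label`).
#' @param call Unquoted column of predicted labels (default `call`).
#' @param positive The positive class. Defaults to `"higher_risk"` or
#'   `"cancer"` when present in the truth column.
#' @return Object of class `"confusion_summary"`: counts `tp`, `fp`, `fn`,
#'   `tn` and a metric table; see [tidy.confusion_summary()].
#' @examples
#' d <- tibble::tibble(
#'   label = rep(c("higher_risk", "lower_risk"), c(4, 4)),
#'   call = c("higher_risk", "higher_risk", "higher_risk", "lower_risk",
#'            "lower_risk", "lower_risk", "higher_risk", "lower_risk")
#' )
#' confusion_summary(d)
#' @export
confusion_summary <- function(data, truth = label, call = call,
                              positive = NULL) {
  tr <- as.character(dplyr::pull(data, {{ truth }}))
  cl <- as.character(dplyr::pull(data, {{ call }}))
  if (length(tr) != length(cl)) {
    rlang::abort("Truth and call columns must have equal length.")
  }
  keep <- !is.na(tr) & !is.na(cl) & tr != "unknown" & cl != "unknown"
  if (sum(!keep) > 0L) {
    rlang::inform(sprintf(
      "Dropping %d sample(s) with unknown truth or call.", sum(!keep)
    ))
  }
  tr <- tr[keep]
  cl <- cl[keep]
  lev <- sort(unique(c(tr, cl)))
  if (length(lev) > 2L) {
    rlang::abort(sprintf(
      "Labels must be binary after dropping unknowns; found %s.",
      paste(lev, collapse = ", ")
    ))
  }
  positive <- positive %||% intersect(c("higher_risk", "cancer"), lev)[1]
  if (is.na(positive)) {
    rlang::abort(sprintf(
      "Cannot infer the positive class from %s; pass `positive`.",
      paste(sQuote(lev), collapse = ", ")
    ))
  }
  if (!any(tr == positive)) {
    rlang::abort("No positive-class samples in truth; sensitivity is undefined.")
  }
  tp <- sum(cl == positive & tr == positive)
  fp <- sum(cl == positive & tr != positive)
  fn <- sum(cl != positive & tr == positive)
  tn <- sum(cl != positive & tr != positive)
  new_confusion_summary(tp, fp, fn, tn, positive,
    negative = setdiff(lev, positive) %||% "negative"
  )
}

#' Confusion summary from raw 2x2 counts
#'
#' Builds the same object as [confusion_summary()] directly from the four
#' cells of a published contingency table, so printed tables can be
#' re-evaluated without patient-level data.
#'
#' @param tp,fp,fn,tn Cell counts (positive class down, calls across).
#' @param positive,negative Class names used in reports.
#' @return A `"confusion_summary"` object.
#' @examples
#' confusion_from_counts(tp = 124, fp = 11, fn = 25, tn = 42)
#' @export
confusion_from_counts <- function(tp, fp, fn, tn,
                                  positive = "higher_risk",
                                  negative = "lower_risk") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("Counts must be non-negative integers.")
  }
  if (tp + fn == 0) {
    rlang::abort("No positive-class samples; sensitivity is undefined.")
  }
  new_confusion_summary(tp, fp, fn, tn, positive, negative)
}

#' @noRd
new_confusion_summary <- function(tp, fp, fn, tn, positive, negative) {
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
  den <- c(
    sensitivity = tp + fn, specificity = tn + fp,
    ppv = tp + fp, npv = tn + fn
  )
  metrics <- purrr::map2(num, den, function(k, n) {
    if (n == 0) {
      tibble::tibble(
        k = k, n = n, estimate = NA_real_,
        conf.low = NA_real_, conf.high = NA_real_
      )
    } else {
      wald_interval(k, n)
    }
  }) |>
    dplyr::bind_rows(.id = "metric") |>
    dplyr::rename(numerator = "k", denominator = "n")
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      positive = positive, negative = negative,
      metrics = metrics
    ),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "<confusion_summary> positive = %s | tp %d, fp %d, fn %d, tn %d\n",
    x$positive, x$tp, x$fp, x$fn, x$tn
  ))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-11s %s\n", m$metric[i],
      format_metric(m$estimate[i], m$conf.low[i], m$conf.high[i])
    ))
  }
  invisible(x)
}

# Percent rounding is half-up to 2 decimals and applied only at rendering.
#' @noRd
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# "83.22 (89.22-77.22)%", upper bound first, as the published tables print.
#' @noRd
format_metric <- function(estimate, lower, upper) {
  if (is.na(estimate)) return("NA")
  sprintf(
    "%.2f (%.2f–%.2f)%%",
    round_half_up(estimate), round_half_up(upper), round_half_up(lower)
  )
}

#' Render a diagnostic performance table
#'
#' Lays out one or more confusion summaries the way published panel
#' evaluations print them: the 2x2 counts, then sensitivity, specificity,
#' PPV and NPV as `"point (upper–lower)%"` with percentages rounded half-up
#' to two decimals.
#'
#' @param summaries A single [confusion_summary()] or a named list of them
#'   (one column per summary).
#' @return Tibble with a `quantity` column and one character column per
#'   summary.
#' @examples
#' performance_table(list(
#'   `14-Gene Panel` = confusion_from_counts(124, 11, 25, 42)
#' ))
#' @export
performance_table <- function(summaries) {
  if (inherits(summaries, "confusion_summary")) {
    summaries <- list(panel = summaries)
  }
  if (length(summaries) == 0L) rlang::abort("Need at least one summary.")
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    names(summaries) <- paste0("panel_", seq_along(summaries))
  }
  rows <- c(
    "True positive", "False negative", "False positive", "True negative",
    "Sensitivity (95% CI)", "Specificity (95% CI)",
    "PPV (95% CI)", "NPV (95% CI)"
  )
  cols <- purrr::map(summaries, function(s) {
    m <- s$metrics
    get <- function(metric) {
      i <- which(m$metric == metric)
      format_metric(m$estimate[i], m$conf.low[i], m$conf.high[i])
    }
    c(
      as.character(c(s$tp, s$fn, s$fp, s$tn)),
      get("sensitivity"), get("specificity"), get("ppv"), get("npv")
    )
  })
  dplyr::bind_cols(tibble::tibble(quantity = rows), tibble::as_tibble(cols))
}

#' ROC curve by threshold sweep
#'
#' Sweeps every unique score as a decision threshold (higher score means
#' more positive), producing the full (FPR, TPR) staircase from (0, 0) to
#' (1, 1), the trapezoidal AUC, and a Hanley–McNeil 95% interval. The
#' trapezoidal AUC with this tie handling equals the Mann–Whitney
#' concordance probability (ties counted half); the equality is part of the
#' contract and is property-tested.
#'
#' @param data Tibble holding score and truth columns.
#' @param score Unquoted numeric score column (default `d_score`).
#' @param truth Unquoted truth column (default `label`).
#' @param positive Positive class; defaults as in [confusion_summary()].
#' @return Object of class `"panel_roc"`: `points` (threshold, fpr, tpr),
#'   `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @examples
#' d <- tibble::tibble(label = c("a", "a", "b", "b"), d_score = c(3, 2, 1, 2))
#' roc_curve(d, positive = "a")$auc # 0.875
#' @export
roc_curve <- function(data, score = d_score, truth = label, positive = NULL) {
  s <- dplyr::pull(data, {{ score }})
  tr <- as.character(dplyr::pull(data, {{ truth }}))
  keep <- !is.na(s) & !is.na(tr) & tr != "unknown"
  s <- s[keep]
  tr <- tr[keep]
  lev <- sort(unique(tr))
  positive <- positive %||% intersect(c("higher_risk", "cancer"), lev)[1]
  if (is.na(positive) || !positive %in% lev) {
    rlang::abort(sprintf(
      "`positive` must be one of %s.", paste(sQuote(lev), collapse = ", ")
    ))
  }
  y <- tr == positive
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    rlang::abort("ROC needs at least one positive and one negative sample.")
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]
  y_ord <- y[ord]
  # one step per unique score: cumulative counts after including that group
  last_of_group <- rev(!duplicated(rev(s_ord)))
  tp <- cumsum(y_ord)[last_of_group]
  fp <- cumsum(!y_ord)[last_of_group]
  points <- tibble::tibble(
    threshold = c(Inf, s_ord[last_of_group]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- trapezoid_area(points$fpr, points$tpr)
  ci <- auc_interval(auc, n_pos, n_neg)
  structure(
    list(
      points = points, auc = auc,
      auc_ci = c(lower = ci$conf.low, upper = ci$conf.high),
      auc_se = ci$se,
      n_pos = n_pos, n_neg = n_neg, positive = positive
    ),
    class = "panel_roc"
  )
}

#' @noRd
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.panel_roc <- function(x, ...) {
  cat(sprintf(
    "<panel_roc> AUC %.3f (95%% CI %.3f–%.3f) | %d positive, %d negative\n",
    x$auc, x$auc_ci[["upper"]], x$auc_ci[["lower"]], x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Hanley–McNeil interval for an AUC
#'
#' Standard error of a trapezoidal AUC from the Hanley–McNeil
#' exponential-approximation formula, with a normal 95% interval clipped to
#' \[0, 1\] (an AUC is a probability, unlike the percent metrics whose
#' published intervals are unclipped).
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg Group sizes.
#' @param z Normal quantile, default 1.96.
#' @return Tibble with `estimate`, `se`, `conf.low`, `conf.high`.
#' @examples
#' auc_interval(0.875, 20, 20)
#' @export
auc_interval <- function(auc, n_pos, n_neg, z = 1.96) {
  if (auc < 0 || auc > 1) rlang::abort("`auc` must lie in [0, 1].")
  if (n_pos < 1 || n_neg < 1) rlang::abort("Both group sizes must be >= 1.")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt(
    (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  )
  tibble::tibble(
    estimate = auc, se = se,
    conf.low = max(0, auc - z * se),
    conf.high = min(1, auc + z * se)
  )
}

#' Per-gene two-sample t-tests of differential expression
#'
#' Compares each panel gene's normalized expression between the two groups,
#' reporting group means (on the scale of the input, conventionally x1,000
#' CtS), their difference, the t statistic and two-sided p-value. Welch's
#' unequal-variance test is the default; the pooled-variance variant is
#' available via `var_equal = TRUE`. No multiple-testing correction is
#' applied, matching the source analysis style.
#'
#' @param data Profile tibble with a label column and gene columns.
#' @param genes Panel restriction; defaults to 14-panel columns present.
#' @param label Unquoted label column (default `label`).
#' @param group_a,group_b The two labels to compare (difference is A minus
#'   B). Default: positive class first (`higher_risk`/`cancer` when
#'   present).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return Tibble: `gene`, `n_a`, `n_b`, `mean_a`, `mean_b`, `difference`,
#'   `statistic`, `p.value`, `significant`.
#' @examples
#' profiles <- simulate_profiles(sim_config(seed = 1))
#' gene_ttests(profiles)
#' @export
gene_ttests <- function(data, genes = NULL, label = label,
                        group_a = NULL, group_b = NULL,
                        var_equal = FALSE, alpha = 0.05) {
  genes <- resolve_genes(data, genes)
  labels <- as.character(dplyr::pull(data, {{ label }}))
  keep <- !is.na(labels) & labels != "unknown"
  labels <- labels[keep]
  data <- data[keep, , drop = FALSE]
  lev <- sort(unique(labels))
  group_a <- group_a %||% intersect(c("higher_risk", "cancer"), lev)[1]
  if (is.na(group_a)) group_a <- lev[1]
  group_b <- group_b %||% setdiff(lev, group_a)[1]
  if (!all(c(group_a, group_b) %in% lev)) {
    rlang::abort(sprintf(
      "Groups must be among %s.", paste(sQuote(lev), collapse = ", ")
    ))
  }
  in_a <- labels == group_a
  in_b <- labels == group_b
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    rlang::abort("Each group needs at least 2 samples for a t-test.")
  }
  purrr::map(genes, function(g) {
    xa <- data[[g]][in_a]
    xb <- data[[g]][in_b]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      rlang::abort(sprintf(
        "Gene %s has zero variance in both groups; t-test undefined.", g
      ))
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    tibble::tibble(
      gene = g,
      n_a = length(xa), n_b = length(xb),
      mean_a = mean(xa), mean_b = mean(xb),
      difference = mean(xa) - mean(xb),
      statistic = unname(tt$statistic),
      p.value = tt$p.value,
      significant = tt$p.value < alpha
    )
  }) |>
    dplyr::bind_rows()
}
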
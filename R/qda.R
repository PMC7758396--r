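#' Fit the two-class quadratic discriminant panel model
#'
#' Fits class-conditional Gaussians to the panel's normalized expression
#' values and expands each class's log density plus log prior into an
#' explicit polynomial — a constant, one coefficient per gene, and one
#' coefficient per gene pair — of the form
#'
#' \deqn{C_k(x) = A_k + \sum_i x_i H_i + \sum_{i \le j} x_i x_j H_{i j}}
#'
#' so the fitted classifier is exactly the printed "D Score" form: the score
#' of a sample is `C_positive(x) - C_negative(x)`, and the positive class
#' (higher-risk, or cancer) is called when the D Score exceeds zero.
#' Internally \eqn{C_k(x) = \log \pi_k - \frac12 \log |\Sigma_k| -
#' \frac12 (x-\mu_k)^\top \Sigma_k^{-1} (x-\mu_k)}; the expansion identity is
#' part of the object's contract and is exercised by the test suite.
#'
#' Covariances are the unbiased per-class estimates, optionally shrunk
#' toward the diagonal of the pooled covariance:
#' \eqn{\Sigma_k(\lambda) = (1-\lambda) \Sigma_k + \lambda\,
#' \mathrm{diag}(\Sigma_{pooled})}. With 14 genes and a small negative
#' class, a little shrinkage keeps the covariances well conditioned;
#' `shrinkage = 0` gives classical QDA.
#'
#' @param data Profile tibble: one row per patient, a label column, one
#'   column per panel gene (CtS values; either scale).
#' @param genes Panel (see [panel_genes()]); defaults to the 14-gene panel
#'   columns present in `data`.
#' @param label Unquoted label column (default `label`).
#' @param positive_class Label treated as the positive class. Defaults to
#'   `"higher_risk"` or `"cancer"` when present.
#' @param prior_mode `"proportional"` (class frequencies, default) or
#'   `"equal"`.
#' @param shrinkage Covariance shrinkage weight in `[0, 1]`, default 0.1.
#' @param task `"stratification"` or `"diagnosis"` — a tag carried into
#'   reports; the machinery is identical.
#' @return An object of class `"panel_model"`; see [tidy.panel_model()] for
#'   the coefficient table and [write_panel_model()] for serialization.
#' @examples
#' profiles <- simulate_profiles(sim_config(seed = 1))
#' fit_panel_model(profiles)
#' @export
fit_panel_model <- function(data, genes = NULL, label = label,
                            positive_class = NULL,
                            prior_mode = c("proportional", "equal"),
                            shrinkage = 0.1,
                            task = c("stratification", "diagnosis")) {
  prior_mode <- rlang::arg_match(prior_mode)
  task <- rlang::arg_match(task)
  if (shrinkage < 0 || shrinkage > 1) {
    rlang::abort("`shrinkage` must lie in [0, 1].")
  }
  genes <- resolve_genes(data, genes)
  labels <- dplyr::pull(data, {{ label }})
  keep <- !is.na(labels) & labels != "unknown"
  if (sum(!keep) > 0L) {
    rlang::inform(sprintf("Dropping %d sample(s) with unknown label.", sum(!keep)))
  }
  labels <- as.character(labels[keep])
  x <- as.matrix(data[keep, genes, drop = FALSE])
  storage.mode(x) <- "double"
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    rlang::abort(sprintf(
      "Need exactly 2 classes; found %d (%s).", length(classes),
      paste(classes, collapse = ", ")
    ))
  }
  positive_class <- positive_class %||%
    intersect(c("higher_risk", "cancer"), classes)[1]
  if (is.na(positive_class) || !positive_class %in% classes) {
    rlang::abort(sprintf(
      "`positive_class` must be one of %s.", paste(sQuote(classes), collapse = ", ")
    ))
  }
  negative_class <- setdiff(classes, positive_class)
  ord <- c(positive_class, negative_class)

  n_k <- vapply(ord, function(cl) sum(labels == cl), integer(1))
  if (any(n_k < 2L)) {
    rlang::abort("Each class needs more than one sample to estimate a covariance.")
  }
  priors <- switch(prior_mode,
    proportional = n_k / sum(n_k),
    equal = stats::setNames(rep(0.5, 2), ord)
  )

  means <- lapply(ord, function(cl) colMeans(x[labels == cl, , drop = FALSE]))
  covs_raw <- lapply(ord, function(cl) stats::cov(x[labels == cl, , drop = FALSE]))
  names(means) <- names(covs_raw) <- ord
  pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs_raw, n_k)) /
    (sum(n_k) - 2)
  covs <- lapply(covs_raw, function(S) {
    (1 - shrinkage) * S + shrinkage * diag(diag(pooled), nrow(S))
  })
  names(covs) <- ord

  comp <- lapply(ord, function(cl) {
    S <- covs[[cl]]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
      rlang::abort(sprintf(
        paste0(
          "Covariance of class '%s' is singular or near-singular; ",
          "increase `shrinkage` (currently %.3g) or reduce the panel."
        ),
        cl, shrinkage
      ))
    }
    inv <- chol2inv(ch)
    mu <- means[[cl]]
    list(
      quad = -0.5 * inv,
      linear = drop(inv %*% mu),
      constant = log(priors[[cl]]) - sum(log(diag(ch))) -
        0.5 * drop(mu %*% inv %*% mu),
      log_det = 2 * sum(log(diag(ch)))
    )
  })
  names(comp) <- ord

  structure(
    list(
      panel = genes,
      task = task,
      classes = stats::setNames(ord, c("positive", "negative")),
      priors = priors,
      prior_mode = prior_mode,
      shrinkage = shrinkage,
      n_per_class = n_k,
      constant = vapply(comp, `[[`, numeric(1), "constant"),
      linear = matrix(
        unlist(lapply(comp, `[[`, "linear")),
        nrow = length(genes), dimnames = list(genes, ord)
      ),
      quad = lapply(comp, function(z) {
        Q <- z$quad
        dimnames(Q) <- list(genes, genes)
        Q
      }),
      log_det = vapply(comp, `[[`, numeric(1), "log_det"),
      class_means = means,
      class_covariances = covs
    ),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf(
    "<panel_model> %s | %d genes | %s (n=%d) vs %s (n=%d)\n",
    x$task, length(x$panel),
    x$classes[["positive"]], x$n_per_class[[1]],
    x$classes[["negative"]], x$n_per_class[[2]]
  ))
  cat(sprintf(
    "  priors: %s | shrinkage: %.3g\n",
    paste(sprintf("%s=%.3f", names(x$priors), x$priors), collapse = ", "),
    x$shrinkage
  ))
  cat("  D Score = C_positive(x) - C_negative(x); call positive when D > 0\n")
  invisible(x)
}

# Polynomial class scores: constant + linear'x + x'Qx, one column per class.
#' @noRd
class_scores <- function(model, x) {
  sc <- vapply(names(model$constant), function(cl) {
    model$constant[[cl]] + drop(x %*% model$linear[, cl]) +
      rowSums((x %*% model$quad[[cl]]) * x)
  }, numeric(nrow(x)))
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = 1L, dimnames = list(NULL, names(sc)))
  sc
}

# Reference route: Gaussian log-density + log prior, via mahalanobis().
# Kept separate from the polynomial route so the expansion identity is a
# real two-route check.
#' @noRd
class_scores_density <- function(model, x) {
  sc <- vapply(names(model$constant), function(cl) {
    log(model$priors[[cl]]) - 0.5 * model$log_det[[cl]] -
      0.5 * stats::mahalanobis(
        x, model$class_means[[cl]], model$class_covariances[[cl]]
      )
  }, numeric(nrow(x)))
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = 1L, dimnames = list(NULL, names(sc)))
  sc
}

#' Score samples with a fitted panel model
#'
#' Evaluates the two class polynomials and the D Score for each sample.
#' A sample is called the positive class (higher-risk, or cancer) when its
#' D Score is strictly greater than zero; a score of exactly zero is called
#' negative, matching the "> 0" decision rule.
#'
#' @param model A [fit_panel_model()] object.
#' @param data Profile tibble covering the model's panel.
#' @return Tibble with `patient_id` (when present), the truth `label` column
#'   (when present), `c_positive`, `c_negative` (the class scores — for the
#'   stratification task these are the higher-risk and lower-risk
#'   polynomials), `d_score`, and `call`.
#' @examples
#' profiles <- simulate_profiles(sim_config(seed = 1))
#' model <- fit_panel_model(profiles)
#' head(score_panel(model, profiles))
#' @export
score_panel <- function(model, data) {
  stopifnot(inherits(model, "panel_model"))
  missing <- setdiff(model$panel, names(data))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "Cannot score: profile table is missing gene(s) %s.",
      paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(data[, model$panel, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    rlang::abort("Cannot score: non-finite expression values present.")
  }
  sc <- class_scores(model, x)
  d <- sc[, 1L] - sc[, 2L]
  out <- tibble::tibble(
    c_positive = sc[, 1L],
    c_negative = sc[, 2L],
    d_score = d,
    call = ifelse(d > 0, model$classes[["positive"]], model$classes[["negative"]])
  )
  if ("label" %in% names(data)) out <- dplyr::bind_cols(
    tibble::tibble(label = data$label), out
  )
  if ("patient_id" %in% names(data)) out <- dplyr::bind_cols(
    tibble::tibble(patient_id = data$patient_id), out
  )
  out
}

#' Score samples with a cancer-vs-benign diagnosis model
#'
#' Identical machinery to [score_panel()] but asserts that the model carries
#' the `"diagnosis"` task tag, so stratification models are not silently
#' reused for the cancer-vs-benign question.
#'
#' @inheritParams score_panel
#' @return See [score_panel()].
#' @export
diagnose_panel <- function(model, data) {
  stopifnot(inherits(model, "panel_model"))
  if (model$task != "diagnosis") {
    rlang::abort("`diagnose_panel()` requires a model fitted with task = 'diagnosis'.")
  }
  score_panel(model, data)
}

#' Serialize a panel model to an auditable JSON document
#'
#' Writes exactly the quantities of the printed score polynomial — panel
#' order, per-class constants, linear coefficients and the upper triangle of
#' each quadratic coefficient matrix — together with the fitted Gaussian
#' parameters (means, covariances, priors), so a model is portable and can
#' be inspected or refit-checked by hand.
#'
#' @param model A [fit_panel_model()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_panel_model()]
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  p <- length(model$panel)
  ut <- upper.tri(diag(p), diag = TRUE)
  doc <- list(
    format = "urostrat_panel_model",
    version = as.character(utils::packageVersion("urostrat")),
    panel = model$panel,
    task = model$task,
    classes = as.list(model$classes),
    prior_mode = model$prior_mode,
    shrinkage = model$shrinkage,
    n_per_class = as.list(model$n_per_class),
    priors = as.list(model$priors),
    constant = as.list(model$constant),
    linear = lapply(
      stats::setNames(colnames(model$linear), colnames(model$linear)),
      function(cl) stats::setNames(as.list(model$linear[, cl]), model$panel)
    ),
    quad_upper_triangle = lapply(model$quad, function(Q) {
      data.frame(
        gene_i = model$panel[row(Q)[ut]],
        gene_j = model$panel[col(Q)[ut]],
        coefficient = Q[ut]
      )
    }),
    class_means = lapply(model$class_means, function(m) {
      stats::setNames(as.list(m), model$panel)
    }),
    class_covariances = model$class_covariances
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized panel model
#'
#' @param path File written by [write_panel_model()].
#' @return A `"panel_model"` object equivalent to the one serialized.
#' @export
read_panel_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "urostrat_panel_model")) {
    rlang::abort("Not a serialized panel model.")
  }
  genes <- doc$panel
  p <- length(genes)
  classes <- unlist(doc$classes)
  ord <- unname(classes[c("positive", "negative")])
  quad <- lapply(doc$quad_upper_triangle, function(df) {
    Q <- matrix(0, p, p, dimnames = list(genes, genes))
    i <- match(df$gene_i, genes)
    j <- match(df$gene_j, genes)
    Q[cbind(i, j)] <- df$coefficient
    Q[cbind(j, i)] <- df$coefficient
    Q
  })[ord]
  covs <- lapply(doc$class_covariances, function(S) {
    S <- as.matrix(S)
    dimnames(S) <- list(genes, genes)
    S
  })[ord]
  linear <- vapply(ord, function(cl) unlist(doc$linear[[cl]])[genes], numeric(p))
  means <- lapply(doc$class_means, function(m) unlist(m)[genes])[ord]
  structure(
    list(
      panel = genes,
      task = doc$task,
      classes = stats::setNames(ord, c("positive", "negative")),
      priors = unlist(doc$priors)[ord],
      prior_mode = doc$prior_mode,
      shrinkage = doc$shrinkage,
      n_per_class = unlist(doc$n_per_class)[ord],
      constant = unlist(doc$constant)[ord],
      linear = linear,
      quad = quad,
      log_det = vapply(covs, function(S) determinant(S)$modulus[1], numeric(1)),
      class_means = means,
      class_covariances = covs
    ),
    class = "panel_model"
  )
}
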
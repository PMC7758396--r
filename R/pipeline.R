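#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs and options of [run_pipeline()]. Exactly one input
#' source must be given: either `sim` (a [sim_config()], the cohort is
#' simulated) or both `ct_table` and `labels` (paths to delimited files as
#' read by [read_ct_table()] and [read_labels()]).
#'
#' @param sim Optional [sim_config()].
#' @param ct_table,labels Optional input file paths.
#' @param panel Panel preset or gene vector (see [panel_genes()]).
#' @param task `"stratification"` or `"diagnosis"`.
#' @param prior_mode,shrinkage Passed to [fit_panel_model()].
#' @param protocol `"resubstitution"` (default) or `"kfold"`.
#' @param k Number of folds when `protocol = "kfold"` (must be >= 2).
#' @param scale CtS reporting scale, 1 or 1000.
#' @param output_dir Directory for the run's report files; `NULL` skips
#'   writing.
#' @param seed Integer seed controlling fold assignment (and the simulation,
#'   when `sim` is given without its own seed).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(sim = NULL, ct_table = NULL, labels = NULL,
                       panel = "panel14",
                       task = c("stratification", "diagnosis"),
                       prior_mode = c("proportional", "equal"),
                       shrinkage = 0.1,
                       protocol = c("resubstitution", "kfold"),
                       k = 5L,
                       scale = 1000,
                       output_dir = NULL,
                       seed = 1L) {
  task <- rlang::arg_match(task)
  prior_mode <- rlang::arg_match(prior_mode)
  protocol <- rlang::arg_match(protocol)
  has_sim <- !is.null(sim)
  has_files <- !is.null(ct_table) || !is.null(labels)
  if (has_sim == has_files) {
    rlang::abort("Give exactly one input source: `sim`, or `ct_table` + `labels`.")
  }
  if (has_files && (is.null(ct_table) || is.null(labels))) {
    rlang::abort("File input needs both `ct_table` and `labels` paths.")
  }
  if (has_sim && !inherits(sim, "sim_config")) {
    rlang::abort("`sim` must be a sim_config object.")
  }
  if (protocol == "kfold" && k < 2L) {
    rlang::abort("`k` must be at least 2 for k-fold evaluation.")
  }
  structure(
    list(
      sim = sim, ct_table = ct_table, labels = labels,
      panel = panel, task = task, prior_mode = prior_mode,
      shrinkage = shrinkage, protocol = protocol, k = as.integer(k),
      scale = scale, output_dir = output_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @noRd
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("[stage: %s] %s", stage, conditionMessage(e)),
      parent = e
    )
  })
}

#' Run the full stratification/diagnosis pipeline
#'
#' Composes the analysis stages in order: obtain replicate-level Ct data
#' (simulated or from files), average replicates, normalize against the
#' reference gene, fit the quadratic-discriminant panel model, score every
#' sample, and evaluate performance (confusion metrics with Wald intervals,
#' ROC/AUC, per-gene t-tests). With `protocol = "kfold"`, scoring of each
#' sample comes from the model fitted on the other folds (stratified by
#' class, seeded) and per-fold metrics are reported alongside the pooled
#' confusion; resubstitution — fitting and evaluating on the full cohort —
#' is the default and is labelled as such in the run log.
#'
#' When `config$output_dir` is set, the run writes `cts_table.csv`,
#' `panel_model.json`, `scores.csv`, `performance.csv`, `roc_points.csv`,
#' `gene_ttests.csv` and `run_log.txt`. Outputs are deterministic given the
#' configuration.
#'
#' @param config A [run_config()].
#' @return List of class `"pipeline_report"`: `profiles`, `model`, `scores`,
#'   `confusion`, `roc`, `gene_tests`, `performance`, plus `folds` and
#'   `fold_metrics` under the k-fold protocol.
#' @examples
#' cfg <- run_config(
#'   sim = sim_config(n_group_a = 30, n_group_b = 20, seed = 1)
#' )
#' report <- run_pipeline(cfg)
#' report$confusion
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$sim)) {
    sim <- config$sim
    if (is.null(sim$seed)) sim$seed <- config$seed
    profiles <- with_stage("simulate", {
      pr <- simulate_profiles(sim)
      raw <- profiles_to_raw_ct(pr, sim)
      labels_tbl <- pr[, intersect(
        c("patient_id", "label", "psa", "gleason"), names(pr)
      )]
      list(raw = raw, labels = labels_tbl)
    })
    raw <- profiles$raw
    label_tbl <- profiles$labels
    genes <- sim$panel
  } else {
    raw <- with_stage("read_ct_table", read_ct_table(config$ct_table))
    label_tbl <- with_stage("read_labels", read_labels(config$labels))
    genes <- panel_genes(config$panel)
  }

  averaged <- with_stage(
    "average_replicates",
    average_replicates(raw, genes = genes)
  )
  cts <- with_stage(
    "normalize",
    normalize_cts(averaged, scale = config$scale, genes = genes)
  )
  profiles <- with_stage("join_labels", {
    out <- dplyr::inner_join(label_tbl, cts, by = "patient_id")
    if (nrow(out) == 0L) rlang::abort("No patients shared by Ct and label tables.")
    out
  })

  positive <- if (config$task == "diagnosis") "cancer" else "higher_risk"

  if (config$protocol == "resubstitution") {
    model <- with_stage("fit", fit_panel_model(
      profiles,
      genes = genes, positive_class = positive,
      prior_mode = config$prior_mode, shrinkage = config$shrinkage,
      task = config$task
    ))
    scores <- with_stage("score", score_panel(model, profiles))
    folds <- NULL
    fold_metrics <- NULL
  } else {
    kf <- with_stage("kfold", kfold_scores(profiles, genes, positive, config))
    model <- kf$full_model
    scores <- kf$scores
    folds <- kf$folds
    fold_metrics <- kf$fold_metrics
  }

  confusion <- with_stage(
    "evaluate",
    confusion_summary(scores, positive = positive)
  )
  roc <- with_stage("evaluate", roc_curve(scores, positive = positive))
  gene_tests <- with_stage("evaluate", gene_ttests(profiles, genes = genes))
  perf <- performance_table(stats::setNames(
    list(confusion), paste0(length(genes), "-gene panel")
  ))

  report <- structure(
    list(
      config = config, profiles = profiles, model = model, scores = scores,
      confusion = confusion, roc = roc, gene_tests = gene_tests,
      performance = perf, folds = folds, fold_metrics = fold_metrics
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$output_dir)) {
    with_stage("write_outputs", write_report(report, config$output_dir))
  }
  report
}

# Stratified k-fold: each sample is scored by the model fitted without its
# fold; the pooled confusion uses these out-of-fold calls.
#' @noRd
kfold_scores <- function(profiles, genes, positive, config) {
  labels <- profiles$label
  k <- config$k
  fold <- integer(nrow(profiles))
  withr::with_seed(config$seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        rlang::abort(sprintf(
          "Class '%s' has %d samples, fewer than k = %d folds.",
          cl, length(idx), k
        ))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  scores <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    train <- profiles[fold != f, , drop = FALSE]
    test <- profiles[fold == f, , drop = FALSE]
    m <- fit_panel_model(
      train,
      genes = genes, positive_class = positive,
      prior_mode = config$prior_mode, shrinkage = config$shrinkage,
      task = config$task
    )
    sc <- score_panel(m, test)
    sc$fold <- f
    scores[[f]] <- sc
    cs <- confusion_summary(sc, positive = positive)
    fold_metrics[[f]] <- tibble::tibble(
      fold = f, n = nrow(sc),
      tp = cs$tp, fp = cs$fp, fn = cs$fn, tn = cs$tn
    )
  }
  full_model <- fit_panel_model(
    profiles,
    genes = genes, positive_class = positive,
    prior_mode = config$prior_mode, shrinkage = config$shrinkage,
    task = config$task
  )
  scores <- dplyr::bind_rows(scores) |>
    dplyr::arrange(match(.data$patient_id, profiles$patient_id))
  list(
    full_model = full_model, scores = scores,
    folds = tibble::tibble(patient_id = profiles$patient_id, fold = fold),
    fold_metrics = dplyr::bind_rows(fold_metrics)
  )
}

#' @noRd
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- report$config
  readr::write_csv(report$profiles, file.path(dir, "cts_table.csv"),
    progress = FALSE
  )
  write_panel_model(report$model, file.path(dir, "panel_model.json"))
  readr::write_csv(report$scores, file.path(dir, "scores.csv"),
    progress = FALSE
  )
  readr::write_csv(report$performance, file.path(dir, "performance.csv"),
    progress = FALSE
  )
  readr::write_csv(report$roc$points, file.path(dir, "roc_points.csv"),
    progress = FALSE
  )
  readr::write_csv(report$gene_tests, file.path(dir, "gene_ttests.csv"),
    progress = FALSE
  )
  if (!is.null(report$fold_metrics)) {
    readr::write_csv(report$fold_metrics, file.path(dir, "fold_metrics.csv"),
      progress = FALSE
    )
  }
  log_lines <- c(
    sprintf("urostrat version: %s", utils::packageVersion("urostrat")),
    sprintf("task: %s", cfg$task),
    sprintf("panel: %s", paste(report$model$panel, collapse = ",")),
    sprintf(
      "protocol: %s%s", cfg$protocol,
      if (cfg$protocol == "kfold") sprintf(" (k = %d)", cfg$k) else ""
    ),
    sprintf("prior_mode: %s", cfg$prior_mode),
    sprintf("shrinkage: %g", cfg$shrinkage),
    sprintf("scale: %g", cfg$scale),
    sprintf("seed: %d", cfg$seed),
    sprintf(
      "auc: %.6f (95%% CI %.6f-%.6f)", report$roc$auc,
      report$roc$auc_ci[["lower"]], report$roc$auc_ci[["upper"]]
    )
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> %s | %d samples | protocol %s\n",
    x$config$task, nrow(x$profiles), x$config$protocol
  ))
  print(x$confusion)
  print(x$roc)
  invisible(x)
}
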
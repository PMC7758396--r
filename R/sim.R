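#' Configuration for a synthetic urinary-qPCR cohort
#'
#' Builds the parameter set for [simulate_profiles()] and
#' [profiles_to_raw_ct()]. Defaults describe the two-group structure of the
#' prospective urine risk-stratification cohort: 149 higher-risk and 53
#' lower-risk patients, with per-gene group mean differences (on the x1,000
#' normalized CtS scale) matching the reported differential expression of the
#' nine significantly shifted genes (CST3 +1008, VEGFA +953, GOLM1 +813,
#' CCND1 +727, LMTK2 +552, PMP22 +534, TMPRSS2 +523, PIP5K1A -274,
#' PTEN -121). The five remaining genes (CDK1, EZH2, PCA3, ANXA3, GSTP1)
#' receive |delta| = 60 with a standard deviation calibrated so that a
#' two-sample t-test at the default group sizes rejects roughly half the
#' time — large but not reliably significant shifts.
#'
#' `task = "diagnosis"` switches to a cancer-vs-benign labelling scheme
#' (202 cancer vs 191 benign) with an arbitrary default effect vector of
#' 0.6 x the stratification deltas; no published effect sizes exist for the
#' benign comparison, so treat those defaults as plumbing, not calibration.
#'
#' @param panel Gene symbols (see [panel_genes()]).
#' @param n_group_a,n_group_b Group sizes. Group A is the positive class
#'   (higher-risk, or cancer), group B the negative class.
#' @param mu_b Named per-gene baseline means for group B on the x1,000 CtS
#'   scale. Defaults place the two group means at Ct of roughly 15-40 cycles
#'   given the default actin Ct of 25.
#' @param delta Named per-gene mean shift, group A minus group B, x1,000 CtS
#'   scale.
#' @param sigma Named per-gene within-group standard deviation, x1,000 CtS
#'   scale.
#' @param correlation Single exchangeable within-group gene-gene correlation.
#' @param actin_ct_mean,actin_ct_sd Mean and patient-level SD of the
#'   beta-actin reference Ct, in cycles.
#' @param replicate_sd Additive technical noise per PCR replicate, in cycles.
#' @param n_replicates Number of PCR replicates per (patient, gene).
#' @param task `"stratification"` (higher/lower risk) or `"diagnosis"`
#'   (cancer/benign).
#' @param covariates If `TRUE`, attach synthetic PSA and Gleason covariates
#'   (drawn independently of group, for pipeline plumbing and subgroup
#'   bookkeeping only — they carry no calibrated signal).
#' @param seed Integer seed; every simulation from the same config is
#'   bitwise reproducible. `NULL` uses the current RNG state.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$delta[["CST3"]]
#' @export
sim_config <- function(panel = "panel14",
                       n_group_a = NULL,
                       n_group_b = NULL,
                       mu_b = NULL,
                       delta = NULL,
                       sigma = NULL,
                       correlation = 0,
                       actin_ct_mean = 25,
                       actin_ct_sd = 1,
                       replicate_sd = 0.15,
                       n_replicates = 3,
                       task = c("stratification", "diagnosis"),
                       covariates = TRUE,
                       seed = NULL) {
  task <- rlang::arg_match(task)
  genes <- panel_genes(panel)
  p <- length(genes)

  default_delta <- c(
    PMP22 = 534, GOLM1 = 813, LMTK2 = 552, EZH2 = 60, GSTP1 = -60,
    PCA3 = 60, VEGFA = 953, CST3 = 1008, PTEN = -121, PIP5K1A = -274,
    CDK1 = 60, TMPRSS2 = 523, ANXA3 = -60, CCND1 = 727
  )
  insignificant <- c("EZH2", "GSTP1", "PCA3", "CDK1", "ANXA3")

  if (is.null(delta)) {
    delta <- default_delta[genes]
    delta[is.na(delta)] <- 0
    names(delta) <- genes
    if (task == "diagnosis") delta <- 0.6 * delta
  } else {
    delta <- expand_gene_param(delta, genes, "delta")
  }

  if (is.null(sigma)) {
    # 191 makes the Welch-t noncentrality at 149/53 with |delta| = 60 sit at
    # the 5% critical value (~50% rejection); 200 keeps significant genes
    # well inside the positive CtS range.
    sigma <- stats::setNames(rep(200, p), genes)
    sigma[intersect(insignificant, genes)] <- 191
  } else {
    sigma <- expand_gene_param(sigma, genes, "sigma")
  }

  if (is.null(mu_b)) {
    base <- default_delta[genes]
    base[is.na(base)] <- 0
    mu_b <- pmax(1100 - base / 2, 650)
    names(mu_b) <- genes
  } else {
    mu_b <- expand_gene_param(mu_b, genes, "mu_b")
  }

  if (is.null(n_group_a)) n_group_a <- if (task == "diagnosis") 202L else 149L
  if (is.null(n_group_b)) n_group_b <- if (task == "diagnosis") 191L else 53L

  labels <- if (task == "diagnosis") {
    c(a = "cancer", b = "benign")
  } else {
    c(a = "higher_risk", b = "lower_risk")
  }

  cfg <- structure(
    list(
      panel = genes, n_group_a = as.integer(n_group_a),
      n_group_b = as.integer(n_group_b), mu_b = mu_b, delta = delta,
      sigma = sigma, correlation = correlation,
      actin_ct_mean = actin_ct_mean, actin_ct_sd = actin_ct_sd,
      replicate_sd = replicate_sd, n_replicates = as.integer(n_replicates),
      task = task, labels = labels, covariates = isTRUE(covariates),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @noRd
expand_gene_param <- function(x, genes, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(genes)), genes))
  }
  if (is.null(names(x)) && length(x) == length(genes)) {
    return(stats::setNames(as.numeric(x), genes))
  }
  missing <- setdiff(genes, names(x))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "`%s` is missing value(s) for gene(s): %s.", what,
      paste(missing, collapse = ", ")
    ))
  }
  as.numeric(x[genes]) |> stats::setNames(genes)
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_group_a < 2L || cfg$n_group_b < 2L) {
    rlang::abort("Both group sizes must be at least 2.")
  }
  if (any(cfg$sigma <= 0)) {
    rlang::abort("All per-gene `sigma` values must be positive.")
  }
  if (cfg$n_replicates < 1L) {
    rlang::abort("`n_replicates` must be at least 1.")
  }
  if (cfg$replicate_sd < 0 || cfg$actin_ct_sd < 0) {
    rlang::abort("Noise standard deviations must be non-negative.")
  }
  p <- length(cfg$panel)
  rho <- cfg$correlation
  if (p > 1L && (rho <= -1 / (p - 1) || rho >= 1)) {
    rlang::abort(sprintf(
      paste0(
        "Exchangeable correlation %.3f does not give a positive-definite ",
        "covariance for %d genes (needs %.3f < correlation < 1)."
      ),
      rho, p, -1 / (p - 1)
    ))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s: %d %s + %d %s, %d genes\n",
    x$task, x$n_group_a, x$labels[["a"]], x$n_group_b, x$labels[["b"]],
    length(x$panel)
  ))
  cat(sprintf(
    "  correlation %.2f | actin Ct %.1f (sd %.2f) | %d replicates (sd %.2f)\n",
    x$correlation, x$actin_ct_mean, x$actin_ct_sd, x$n_replicates,
    x$replicate_sd
  ))
  invisible(x)
}

#' Simulate per-patient normalized expression profiles
#'
#' Draws a two-group cohort of per-patient CtS vectors (x1,000 scale) from a
#' multivariate Gaussian with exchangeable within-group correlation.
#' Rows whose draw contains a non-positive expression value are redrawn, so
#' every profile satisfies the strict-positivity invariant of the CtS scale;
#' at the default parameters the redraw probability is below 0.1% per
#' patient, so calibration is essentially unaffected.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per patient: `patient_id`, `label`, optional
#'   `psa` and `gleason` covariates, then one column per panel gene.
#' @examples
#' profiles <- simulate_profiles(sim_config(seed = 1))
#' dplyr::count(profiles, label)
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  run <- function() {
    a <- draw_group(config$n_group_a, config$mu_b + config$delta, config)
    b <- draw_group(config$n_group_b, config$mu_b, config)
    n <- config$n_group_a + config$n_group_b
    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      label = rep(c(config$labels[["a"]], config$labels[["b"]]),
        times = c(config$n_group_a, config$n_group_b)
      )
    )
    if (config$covariates) {
      out$psa <- stats::rlnorm(n, meanlog = log(12), sdlog = 0.9)
      out$gleason <- sample(
        c("<=6", "3+4", "4+3", "8", "9-10"),
        size = n, replace = TRUE,
        prob = c(52, 42, 41, 36, 31) / 202
      )
    }
    dplyr::bind_cols(out, tibble::as_tibble(rbind(a, b)))
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# Draw n rows from N(mu, Sigma) with exchangeable correlation, redrawing any
# row containing a non-positive value (CtS is strictly positive).
#' @noRd
draw_group <- function(n, mu, config) {
  genes <- config$panel
  p <- length(genes)
  corr <- matrix(config$correlation, p, p)
  diag(corr) <- 1
  sigma <- config$sigma[genes]
  cov <- corr * tcrossprod(sigma)
  chol_cov <- tryCatch(chol(cov), error = function(e) {
    rlang::abort(sprintf(
      "Implied covariance is not positive definite (correlation = %.3f).",
      config$correlation
    ))
  })
  draw <- function(m) {
    z <- matrix(stats::rnorm(m * p), m, p)
    sweep(z %*% chol_cov, 2, mu[genes], "+")
  }
  x <- draw(n)
  for (iter in seq_len(100L)) {
    bad <- which(apply(x <= 0, 1L, any))
    if (length(bad) == 0L) break
    x[bad, ] <- draw(length(bad))
  }
  if (any(x <= 0)) {
    rlang::abort(
      "Could not draw strictly positive profiles; means are too close to zero."
    )
  }
  colnames(x) <- genes
  x
}

#' Expand simulated profiles into replicate-level raw Ct readings
#'
#' Inverts the reference-gene normalization to produce instrument-like
#' input: per patient an actin Ct is drawn, each gene's true Ct is
#' `(CtS / 1000) * actin Ct` (CtS is a Ct ratio, so raw-Ct generation is
#' multiplicative through the actin channel), and `n_replicates` readings per
#' gene — and for actin itself — get additive Gaussian replicate noise in
#' cycles. Averaging replicates and re-normalizing recovers the input CtS up
#' to replicate noise; exactly, when both noise SDs are zero.
#'
#' @param profiles Profile tibble from [simulate_profiles()] (CtS on the
#'   x1,000 scale).
#' @param config The same [sim_config()].
#' @return Long tibble of measurements: `patient_id`, `gene`, `replicate`,
#'   `ct`, including rows for the `ACTB` reference.
#' @examples
#' cfg <- sim_config(n_group_a = 3, n_group_b = 3, seed = 1)
#' raw <- profiles_to_raw_ct(simulate_profiles(cfg), cfg)
#' @export
profiles_to_raw_ct <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$panel
  missing <- setdiff(genes, names(profiles))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "Profiles are missing panel gene(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  run <- function() {
    n <- nrow(profiles)
    actin <- stats::rnorm(n, config$actin_ct_mean, config$actin_ct_sd)
    if (any(actin <= 0)) {
      rlang::abort("Drawn actin Ct <= 0; actin_ct_mean/actin_ct_sd are pathological.")
    }
    cts <- as.matrix(profiles[genes])
    true_ct <- (cts / 1000) * actin
    if (any(true_ct <= 0)) {
      rlang::abort("Implied gene Ct <= 0; config is pathological (check mu_b/sigma).")
    }
    true_all <- cbind(true_ct, ACTB = actin)
    reps <- config$n_replicates
    long <- tidyr::expand_grid(
      patient_id = profiles$patient_id,
      gene = colnames(true_all),
      replicate = seq_len(reps)
    )
    base_ct <- as.vector(t(true_all)) # patient-major, gene within patient
    base <- rep(base_ct, each = reps)
    ct <- base + stats::rnorm(nrow(long), 0, config$replicate_sd)
    # a cycle count cannot be negative: redraw the technical noise for the
    # (rare) replicates whose draw undershoots zero
    for (iter in seq_len(100L)) {
      bad <- which(ct <= 0)
      if (length(bad) == 0L) break
      ct[bad] <- base[bad] + stats::rnorm(length(bad), 0, config$replicate_sd)
    }
    if (any(ct <= 0)) {
      rlang::abort("Replicate noise keeps driving Ct below zero; reduce replicate_sd.")
    }
    long$ct <- ct
    long
  }
  if (is.null(config$seed)) {
    run()
  } else {
    # offset so profile draws and raw-Ct noise use distinct streams
    withr::with_seed(config$seed + 1000003L, run())
  }
}
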
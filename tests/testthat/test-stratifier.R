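# The polynomial expansion of the two-class Gaussian discriminant is the
# classifier's core contract: C_k(x) = A_k + sum_i x_i H_i + sum_ij x_i x_j
# H_ij must equal log prior_k - 1/2 log|Sigma_k| - 1/2 Mahalanobis_k(x).

test_that("polynomial scores equal Gaussian log-density scores on random probes", {
  profiles <- small_cohort(seed = 101)
  model <- fit_panel_model(profiles)
  withr::with_seed(1, {
    probes <- matrix(
      stats::runif(100 * 14, min = 200, max = 2000),
      ncol = 14, dimnames = list(NULL, model$panel)
    )
  })
  poly <- urostrat:::class_scores(model, probes)
  dens <- urostrat:::class_scores_density(model, probes)
  expect_equal(poly, dens, tolerance = 1e-8)
})

test_that("symmetric classes give D scores at zero within tolerance", {
  # same sample moments in both classes: mirrored points around the mean
  base <- matrix(
    c(0, 1, 2, 2, 1, 0, 1, 0, 2, 0, 2, 1),
    ncol = 2
  )
  d <- tibble::tibble(
    label = rep(c("x", "y"), each = 6),
    PMP22 = c(base[, 1], base[, 1]),
    GOLM1 = c(base[, 2], base[, 2])
  )
  m <- fit_panel_model(
    d, genes = c("PMP22", "GOLM1"),
    positive_class = "x", prior_mode = "equal", shrinkage = 0
  )
  sc <- score_panel(m, d)
  expect_true(all(abs(sc$d_score) < 1e-10))
})

test_that("one-gene equal-variance fit reduces to the midpoint rule", {
  d <- unit_gaussian_1d()
  m <- fit_panel_model(
    d, genes = "PMP22", positive_class = "a",
    prior_mode = "equal", shrinkage = 0
  )
  probe <- tibble::tibble(PMP22 = c(-1, 0, 0.5, 1, 2.5))
  sc <- score_panel(m, probe)
  # with equal unit variances the quadratic terms cancel: d(x) = x - 0.5
  expect_equal(sc$d_score, probe$PMP22 - 0.5, tolerance = 1e-10)
  # boundary value is assigned to the negative class (D > 0 rule)
  expect_equal(sc$call[3], "b")
  expect_equal(sc$call[probe$PMP22 > 0.5], rep("a", 2))
})

test_that("fitted class means track the generator within 3 standard errors", {
  cfg <- sim_config(n_group_a = 2000, n_group_b = 2000, seed = 13)
  profiles <- simulate_profiles(cfg)
  m <- fit_panel_model(profiles)
  se <- cfg$sigma / sqrt(2000)
  mu_a <- cfg$mu_b + cfg$delta
  expect_true(all(abs(m$class_means$higher_risk - mu_a) < 3 * se))
  expect_true(all(abs(m$class_means$lower_risk - cfg$mu_b) < 3 * se))
})

test_that("adding a common constant to both class constants changes no call", {
  profiles <- small_cohort(seed = 5)
  m <- fit_panel_model(profiles)
  m2 <- m
  m2$constant <- m$constant + 123.4
  expect_equal(
    score_panel(m2, profiles)$call,
    score_panel(m, profiles)$call
  )
  expect_equal(
    score_panel(m2, profiles)$d_score,
    score_panel(m, profiles)$d_score,
    tolerance = 1e-8
  )
})

test_that("swapping class labels negates every D score", {
  profiles <- small_cohort(seed = 6)
  m_pos <- fit_panel_model(profiles, positive_class = "higher_risk")
  m_neg <- fit_panel_model(profiles, positive_class = "lower_risk")
  expect_equal(
    score_panel(m_neg, profiles)$d_score,
    -score_panel(m_pos, profiles)$d_score,
    tolerance = 1e-10
  )
})

test_that("a common rescaling of all features leaves every call unchanged", {
  profiles <- small_cohort(seed = 7)
  scaled <- dplyr::mutate(
    profiles,
    dplyr::across(dplyr::all_of(panel_genes("panel14")), function(x) x / 1000)
  )
  calls_1000 <- score_panel(fit_panel_model(profiles), profiles)$call
  calls_ratio <- score_panel(fit_panel_model(scaled), scaled)$call
  expect_equal(calls_ratio, calls_1000)
})

test_that("calls agree with an independent QDA implementation", {
  skip_if_not_installed("MASS")
  agreement <- vapply(c(31, 32, 33), function(seed) {
    profiles <- small_cohort(n_a = 120, n_b = 80, seed = seed)
    m <- fit_panel_model(profiles, shrinkage = 0)
    ours <- score_panel(m, profiles)$call
    q <- MASS::qda(
      x = as.matrix(profiles[panel_genes("panel14")]),
      grouping = profiles$label
    )
    theirs <- as.character(
      stats::predict(q, as.matrix(profiles[panel_genes("panel14")]))$class
    )
    mean(ours == theirs)
  }, numeric(1))
  expect_true(all(agreement >= 0.99))
})

test_that("increasing every |delta| does not decrease resubstitution AUC", {
  aucs <- vapply(seq(0.05, 1, length.out = 5), function(f) {
    cfg <- sim_config(n_group_a = 80, n_group_b = 60, seed = 17)
    cfg$delta <- cfg$delta * f
    profiles <- simulate_profiles(cfg)
    m <- fit_panel_model(profiles)
    roc_curve(score_panel(m, profiles))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= -1e-9))
})

test_that("degenerate fits raise instructive errors", {
  profiles <- small_cohort(n_a = 8, n_b = 8, seed = 23)
  # 8 samples per class < 14 features: raw covariance is singular
  expect_error(
    fit_panel_model(profiles, shrinkage = 0),
    "shrinkage"
  )
  expect_silent(fit_panel_model(profiles, shrinkage = 0.5))
  one <- small_cohort(n_a = 20, n_b = 20, seed = 2)[c(1, 21), ]
  expect_error(fit_panel_model(one), "more than one sample")
  m <- fit_panel_model(small_cohort(seed = 3))
  expect_error(
    score_panel(m, small_cohort(seed = 3)[, 1:6]),
    "missing gene"
  )
})

test_that("diagnosis task shares machinery but enforces its tag", {
  cfg <- sim_config(
    task = "diagnosis", n_group_a = 60, n_group_b = 60, seed = 19
  )
  profiles <- simulate_profiles(cfg)
  m <- fit_panel_model(profiles, task = "diagnosis")
  expect_equal(m$classes[["positive"]], "cancer")
  sc <- diagnose_panel(m, profiles)
  expect_equal(sc$d_score, score_panel(m, profiles)$d_score)
  m_strat <- fit_panel_model(small_cohort(seed = 4))
  expect_error(diagnose_panel(m_strat, small_cohort(seed = 4)), "diagnosis")
})

test_that("serialization round-trips the model and its scores", {
  profiles <- small_cohort(seed = 29)
  m <- fit_panel_model(profiles)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_model(m, path)
  m2 <- read_panel_model(path)
  expect_equal(m2$panel, m$panel)
  expect_equal(m2$constant, m$constant, tolerance = 1e-12)
  expect_equal(m2$linear, m$linear, tolerance = 1e-12)
  expect_equal(m2$quad, m$quad, tolerance = 1e-12)
  expect_equal(
    score_panel(m2, profiles)$d_score,
    score_panel(m, profiles)$d_score,
    tolerance = 1e-8
  )
})

test_that("tidy and glance expose the printed-polynomial structure", {
  profiles <- small_cohort(seed = 37)
  m <- fit_panel_model(profiles)
  td <- tidy(m)
  p <- 14
  expect_equal(nrow(td), 2 * (1 + p + p * (p + 1) / 2))
  expect_true(all(c("(constant)", "PMP22", "PMP22:GOLM1") %in% td$term))
  # the tidy monomial coefficients evaluate to the same score as the model
  x <- as.matrix(profiles[1, m$panel])
  for (cl in unique(td$class)) {
    tt <- td[td$class == cl, ]
    mono <- vapply(tt$term, function(term) {
      if (term == "(constant)") return(1)
      genes <- strsplit(term, ":", fixed = TRUE)[[1]]
      prod(x[1, genes])
    }, numeric(1))
    expect_equal(
      sum(mono * tt$estimate),
      unname(urostrat:::class_scores(m, x)[1, cl]),
      tolerance = 1e-8
    )
  }
  g <- glance(m)
  expect_equal(g$n, nrow(profiles))
  expect_equal(g$n_genes, 14)
})
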
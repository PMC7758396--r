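test_that("wald_interval reproduces published near-boundary intervals", {
  # specificity 51/52 and NPV 49/96 from the published performance tables:
  # the upper bound above 100% identifies the unclipped Wald form
  w <- wald_interval(51, 52)
  expect_equal(round(w$estimate, 2), 98.08)
  expect_equal(round(w$conf.low, 2), 94.34)
  expect_equal(round(w$conf.high, 2), 101.81)
  w2 <- wald_interval(49, 96)
  expect_equal(round(c(w2$estimate, w2$conf.low, w2$conf.high), 2),
    c(51.04, 41.04, 61.04)
  )
  # degenerate p-hat: interval collapses, still unclipped
  w3 <- wald_interval(10, 10)
  expect_equal(c(w3$estimate, w3$conf.low, w3$conf.high), c(100, 100, 100))
  expect_error(wald_interval(1, 0), "at least 1")
  expect_error(wald_interval(5, 4), "k <= n")
})

test_that("confusion counts partition the samples", {
  perfect <- vectors_from_counts(10, 0, 0, 10)
  cs <- confusion_summary(perfect)
  expect_equal(c(cs$tp, cs$fn, cs$fp, cs$tn), c(10, 0, 0, 10))

  # published prospective-cohort panel table: 124/25 vs 11/42
  t3 <- confusion_summary(vectors_from_counts(124, 25, 11, 42))
  expect_equal(c(t3$tp, t3$fn, t3$fp, t3$tn), c(124, 25, 11, 42))
  expect_equal(t3$tp + t3$fn + t3$fp + t3$tn, 202)

  all_pos <- tibble::tibble(
    label = rep(c("higher_risk", "lower_risk"), c(3, 2)),
    call = "higher_risk"
  )
  ap <- confusion_summary(all_pos)
  expect_equal(c(ap$fn, ap$tn), c(0, 0))
  expect_true(is.na(ap$metrics$estimate[ap$metrics$metric == "npv"]))

  no_pos <- tibble::tibble(label = "lower_risk", call = "lower_risk")
  expect_error(
    confusion_summary(no_pos, positive = "higher_risk"),
    "sensitivity is undefined"
  )
  unk <- dplyr::mutate(perfect, label = replace(label, 1, "unknown"))
  expect_message(confusion_summary(unk), "Dropping 1")
})

test_that("sensitivity and specificity swap when the positive class swaps", {
  withr::with_seed(8, {
    for (i in 1:5) {
      d <- tibble::tibble(
        label = sample(c("higher_risk", "lower_risk"), 60, replace = TRUE),
        call = sample(c("higher_risk", "lower_risk"), 60, replace = TRUE)
      )
      if (length(unique(d$label)) < 2) next
      a <- tidy(confusion_summary(d, positive = "higher_risk"))
      b <- tidy(confusion_summary(d, positive = "lower_risk"))
      expect_equal(
        a$estimate[a$metric == "sensitivity"],
        b$estimate[b$metric == "specificity"]
      )
      expect_equal(
        a$estimate[a$metric == "ppv"],
        b$estimate[b$metric == "npv"]
      )
    }
  })
})

test_that("PPV is recoverable from sensitivity, specificity and prevalence", {
  withr::with_seed(31, {
    for (i in 1:20) {
      tp <- sample(1:50, 1); fn <- sample(0:50, 1)
      fp <- sample(0:50, 1); tn <- sample(1:50, 1)
      if (tp + fp == 0) next
      cs <- confusion_from_counts(tp, fp, fn, tn)
      m <- tidy(cs)
      sens <- m$estimate[m$metric == "sensitivity"] / 100
      spec <- m$estimate[m$metric == "specificity"] / 100
      prev <- (tp + fn) / (tp + fn + fp + tn)
      bayes_ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
      expect_equal(m$estimate[m$metric == "ppv"] / 100, bayes_ppv,
        tolerance = 1e-12
      )
    }
  })
})

test_that("performance_table renders the published layout", {
  tab <- performance_table(list(
    `14-Gene Panel` = confusion_from_counts(tp = 124, fp = 11, fn = 25, tn = 42)
  ))
  expect_equal(names(tab), c("quantity", "14-Gene Panel"))
  sens_row <- tab[["14-Gene Panel"]][tab$quantity == "Sensitivity (95% CI)"]
  expect_equal(sens_row, "83.22 (89.22–77.22)%")
  # tissue-cohort 8-gene NPV point estimate 3/7
  tab2 <- performance_table(list(
    `8-gene` = confusion_from_counts(tp = 231, fp = 52, fn = 4, tn = 3)
  ))
  npv_row <- tab2[["8-gene"]][tab2$quantity == "NPV (95% CI)"]
  expect_match(npv_row, "^42\\.86 ")
  # single unnamed summary still renders one column
  expect_equal(ncol(performance_table(confusion_from_counts(1, 1, 1, 1))), 2)
})

test_that("percent rendering rounds half-up at 2 decimals", {
  expect_equal(urostrat:::round_half_up(0.125 * 100, 2), 12.5)
  expect_equal(urostrat:::round_half_up(83.225, 2), 83.23)
  expect_equal(urostrat:::round_half_up(83.2249, 2), 83.22)
})

test_that("trapezoidal AUC matches brute-force pairwise concordance", {
  # hand example: positives {3, 2}, negatives {1, 2} -> 0.875
  d <- tibble::tibble(
    label = c("pos", "pos", "neg", "neg"),
    d_score = c(3, 2, 1, 2)
  )
  r <- roc_curve(d, positive = "pos")
  expect_equal(r$auc, 0.875)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)

  # perfectly separated scores
  sep <- tibble::tibble(
    label = rep(c("pos", "neg"), each = 4), d_score = c(5:8, 1:4)
  )
  expect_equal(roc_curve(sep, positive = "pos")$auc, 1.0)

  # all scores tied: chance
  tied <- tibble::tibble(label = rep(c("pos", "neg"), 5), d_score = 2)
  expect_equal(roc_curve(tied, positive = "pos")$auc, 0.5)

  expect_error(
    roc_curve(tibble::tibble(label = "pos", d_score = 1), positive = "pos"),
    "at least one"
  )
})

test_that("AUC equals the Mann-Whitney statistic on random instances", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n_pos <- sample(2:12, 1)
      n_neg <- sample(2:12, 1)
      scores <- sample(1:6, n_pos + n_neg, replace = TRUE) +
        sample(c(0, 0.5), n_pos + n_neg, replace = TRUE)
      lab <- rep(c("pos", "neg"), c(n_pos, n_neg))
      d <- tibble::tibble(label = lab, d_score = scores)
      r <- roc_curve(d, positive = "pos")
      expect_equal(r$auc, pairwise_auc(scores, lab == "pos"),
        tolerance = 1e-12
      )
      expect_true(all(diff(r$points$fpr) >= 0))
      expect_true(all(diff(r$points$tpr) >= 0))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    for (i in 1:5) {
      n <- 40
      lab <- rep(c("pos", "neg"), each = n / 2)
      scores <- stats::rnorm(n, mean = ifelse(lab == "pos", 1, 0))
      d <- tibble::tibble(label = lab, d_score = scores)
      ours <- roc_curve(d, positive = "pos")$auc
      theirs <- as.numeric(pROC::auc(
        pROC::roc(lab, scores, levels = c("neg", "pos"), direction = "<",
                  quiet = TRUE)
      ))
      expect_equal(ours, theirs, tolerance = 1e-12)
    }
  })
})

test_that("Hanley-McNeil interval behaves at the boundaries and midpoint", {
  mid <- auc_interval(0.5, 500, 500)
  expect_equal(mid$conf.high - 0.5, 0.5 - mid$conf.low, tolerance = 1e-12)
  expect_lt(mid$conf.high - mid$conf.low, 0.15)

  one <- auc_interval(1, 50, 50)
  expect_equal(one$se, 0)
  expect_equal(c(one$conf.low, one$conf.high), c(1, 1))

  # direct numeric evaluation of the formula for auc 0.875, n = 2/2
  a <- 0.875
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (q1 - a^2) + (q2 - a^2)) / 4)
  got <- auc_interval(a, 2, 2)
  expect_equal(got$se, se, tolerance = 1e-12)
  expect_equal(got$conf.low, max(0, a - 1.96 * se), tolerance = 1e-12)
  expect_equal(got$conf.high, min(1, a + 1.96 * se), tolerance = 1e-12)
})

test_that("per-gene t-tests report group means, difference and significance", {
  # identical groups: difference 0, p = 1
  d <- tibble::tibble(
    label = rep(c("higher_risk", "lower_risk"), each = 3),
    CST3 = c(1, 2, 3, 1, 2, 3)
  )
  tt <- gene_ttests(d, genes = "CST3")
  expect_equal(tt$difference, 0)
  expect_equal(tt$p.value, 1)
  expect_false(tt$significant)

  # zero variance in both groups is an error, not NaN
  flat <- tibble::tibble(
    label = rep(c("higher_risk", "lower_risk"), each = 2),
    CST3 = c(0, 0, 1, 1)
  )
  expect_error(gene_ttests(flat, genes = "CST3"), "zero variance")

  # Welch vs pooled is a parameter
  profiles <- small_cohort(seed = 44)
  welch <- gene_ttests(profiles, genes = "CST3", var_equal = FALSE)
  pooled <- gene_ttests(profiles, genes = "CST3", var_equal = TRUE)
  expect_false(identical(welch$statistic, pooled$statistic))
  expect_equal(welch$difference, pooled$difference)
})
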
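# Shared fixtures, built in code.

# Small seeded default cohort reused across tests.
small_cohort <- function(n_a = 60, n_b = 40, seed = 42, ...) {
  simulate_profiles(sim_config(n_group_a = n_a, n_group_b = n_b, seed = seed, ...))
}

# Reconstruct per-sample truth/call vectors from a published 2x2 table
# (positive-truth row: tp called positive, fn called negative; etc.), so
# printed contingency tables can be fed through confusion_summary().
vectors_from_counts <- function(tp, fn, fp, tn,
                                positive = "higher_risk",
                                negative = "lower_risk") {
  tibble::tibble(
    label = rep(c(positive, negative), c(tp + fn, fp + tn)),
    call = c(
      rep(c(positive, negative), c(tp, fn)),
      rep(c(positive, negative), c(fp, tn))
    )
  )
}

# Brute-force AUC: mean pairwise concordance with half-credit ties.
pairwise_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Deterministic 1-D two-class training set with exact sample moments:
# class "b" has mean 0, var 1; class "a" has mean 1, var 1.
unit_gaussian_1d <- function(gene = "PMP22") {
  tibble::tibble(
    patient_id = sprintf("U%d", 1:6),
    label = rep(c("a", "b"), each = 3),
    !!gene := c(0, 1, 2, -1, 0, 1)
  )
}
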
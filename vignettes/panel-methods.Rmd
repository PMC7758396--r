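---
title: "Methods: the 14-gene urine panel classifier and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 14-gene urine panel classifier and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urostrat)
```

`urostrat` implements the analysis layer of a urine-based prostate-cancer
risk-stratification assay: qPCR normalization, a quadratic-discriminant
panel classifier with an auditable polynomial form, and the standard
diagnostic-performance toolkit. This vignette documents the model, the
numerical and design choices behind it, what the synthetic cohort
generator does and does not emulate, and the known limitations.

## From raw Ct to expression profiles

The measurement for one patient and one gene is a set of replicate cycle
thresholds (Ct). Three choices define the normalization stage:

* **Replicate aggregation** is the arithmetic mean of the Ct values.
  Replicates are never rejected; pairs whose replicate range exceeds one
  cycle are counted and surfaced as a message so unstable wells can be
  audited, but no QC rule removes data.
* **Reference-gene normalization** divides each gene's mean Ct by the
  beta-actin Ct of the same sample: `CtS = Ct(gene) / Ct(actin)`. This is
  a ratio of cycle numbers, not a ΔCt; no PCR-efficiency correction,
  standard curve or ΔΔCt transform is applied.
* **Scale.** The canonical internal value is the bare ratio (near 1); the
  ×1,000 scale is a presentation convention and the package default for
  reporting. The two conventions appear interchangeably in this
  literature, and the choice is immaterial to classification: a common
  affine rescaling of all features is absorbed exactly by the fitted
  discriminant coefficients, and the test suite asserts that calls are
  identical under either scale.

A quirk of this normalization is worth naming: since a *larger* Ct means
*less* transcript, a gene whose CtS increases in the higher-risk group has
(under fixed actin) fewer transcript copies there. The package takes no
position on the biological direction; it models and reports CtS exactly as
assayed.

## The classifier

The panel classifier is two-class quadratic discriminant analysis (QDA)
over the CtS vector $x \in \mathbb{R}^{14}$. Each class $k$ (higher-risk /
lower-risk, or cancer / benign) is modelled as a Gaussian
$\mathcal{N}(\mu_k, \Sigma_k)$ with prior $\pi_k$, giving the class score

$$C_k(x) = \log \pi_k - \tfrac12 \log |\Sigma_k|
  - \tfrac12 (x - \mu_k)^\top \Sigma_k^{-1} (x - \mu_k),$$

which expands exactly into a constant $A_k$, linear coefficients
$H_i^{(k)} = (\Sigma_k^{-1}\mu_k)_i$ and quadratic coefficients
$H_{ij}^{(k)}$ from $-\tfrac12 \Sigma_k^{-1}$. QDA is the unique standard
estimator whose decision function has exactly this
constant-plus-linear-plus-pairwise polynomial shape, which is why it is
the fitting procedure here; the expansion identity (polynomial route
equals log-density route on random probes, relative tolerance $10^{-8}$)
is enforced by the test suite, and `tidy()` exposes every coefficient. The
decision statistic is the D Score $D(x) = C_{+}(x) - C_{-}(x)$ with the
positive class called when $D > 0$; the boundary $D = 0$ goes to the
negative (lower-risk / benign) class, so the tie-break is conservative for
treatment decisions.

Tunable parameters:

* **`prior_mode`** — `"proportional"` (default) uses class frequencies;
  with the imbalanced cohorts typical of this setting (roughly 3:1
  higher:lower risk) this shifts the boundary toward calling the majority
  class and matches the high-sensitivity / modest-NPV operating points
  seen in published panels of this kind. `"equal"` is available when the
  training prevalence should not inform the call.
* **`shrinkage`** $\lambda \in [0,1]$ (default 0.1) — the class covariance
  used is $(1-\lambda)\,\hat\Sigma_k + \lambda\,
  \mathrm{diag}(\hat\Sigma_{pooled})$. With 14 genes, a lower-risk group
  of a few dozen patients puts the raw covariance near singularity; a
  small pull toward the pooled diagonal keeps it invertible without
  changing the polynomial form. $\lambda = 0$ is classical QDA and is what
  the test suite uses when cross-checking calls against an independent QDA
  implementation (agreement ≥ 99% required).
* **`task`** — `"stratification"` or `"diagnosis"`. The machinery is
  identical; the tag prevents a model fitted for one question being
  silently reused for the other. Whether the original diagnosis algorithm
  is structurally identical to the stratification one is not documented
  anywhere we can check; implementing them as the same estimator with a
  task tag is the parsimonious reading.
* **Training protocol** — resubstitution by default (matching how results
  of this kind are usually reported, with no cross-validation described);
  stratified k-fold is available and clearly labelled in reports. See
  *Limitations* for why this matters.

## Diagnostic evaluation

* **Wald intervals, unclipped.** All four confusion metrics carry
  $100\,(\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n})$. Bounds are *not*
  clipped to [0, 100]: published tables in this field print upper bounds
  above 100% for near-perfect metrics, and reproducing those tables to
  the printed decimal requires the unclipped form. Clipping, Wilson or
  Clopper–Pearson alternatives would be statistically more defensible near
  the boundary but are deliberately not the default because they break
  table reproduction; rounding is half-up to two decimals and applied only
  at rendering.
* **ROC/AUC.** Full threshold sweep over unique scores (higher D Score ⇒
  more positive), trapezoidal area, ties at half credit. So computed, the
  AUC equals the Mann–Whitney concordance probability; the equality (to
  $10^{-12}$) is a property test. The AUC interval is Hanley–McNeil
  (their exponential approximation for $Q_1, Q_2$), clipped to [0, 1]
  since an AUC is a probability. DeLong intervals are out of scope.
* **Per-gene differential expression** is a two-sample t-test per gene,
  Welch by default (the pooled-variance variant is a parameter), two-sided
  p-values, no multiple-testing correction — matching the analysis style
  this package mirrors; add `p.adjust()` downstream if your question needs
  it.
* **Bayes consistency.** PPV and NPV computed from counts are exactly
  recoverable from sensitivity, specificity and prevalence via Bayes'
  rule; this invariant is tested and makes the reported table internally
  coherent.
* **Clinical label derivation.** `derive_risk_label()` encodes the
  guideline-derived binarization: higher-risk iff Gleason total > 7, or
  Gleason pattern 4+3, or stage ≥ T3, or PSA > 20 ng/ml (strict), or more
  than half of biopsy cores positive. Missing criteria never qualify (with
  a warning); a patient with no criteria at all is an error. Subgroup
  analyses (Gleason 6–7 only; the 3+4 vs 4+3 split, where 4+3 is the
  positive class; PSA as a baseline classifier) are plain filters and
  column selections over the same pipeline, not separate implementations.

## The synthetic cohort generator

No patient-level data is publicly available for assays of this kind, so
the generator is a first-class module: every downstream stage is exercised
end to end on cohorts whose ground truth is known.

**What it emulates.** Two groups (149 higher-risk, 53 lower-risk by
default — the split that underlies every published metric table; the
prose in the source literature also mentions a 142/60 split, an internal
inconsistency we resolve in favour of the tables) with per-patient CtS
vectors drawn from a multivariate Gaussian with exchangeable gene–gene
correlation (default 0). Gaussianity is the minimal assumption consistent
with evaluating differential expression by t-tests. The nine significantly
shifted genes use the published group mean differences on the ×1,000
scale (CST3 +1008, VEGFA +953, GOLM1 +813, CCND1 +727, LMTK2 +552, PMP22
+534, TMPRSS2 +523, PIP5K1A −274, PTEN −121). Raw instrument-like data is
generated by inverting the normalization: an actin Ct per patient
(mean 25, SD 1 cycle), gene Ct = (CtS/1000) × actin Ct — multiplicative,
because CtS is a ratio — and additive replicate noise in cycles
(SD 0.15, 3 replicates).

**Defaults chosen where the literature is silent**, fixed once and not
revisited:

* Within-group SDs are unpublished. The five "large but not significant"
  genes (CDK1, EZH2, PCA3, ANXA3, GSTP1) get |delta| = 60 (signs
  arbitrary) with SD 191, calibrated so the Welch t noncentrality at
  149/53 sits at the 5% critical value — such a gene rejects in roughly
  half of replicate cohorts, preserving "large yet not reliably
  significant" without inventing effect sizes as facts. The significant
  genes get SD 200 (≈ 5 cycles at actin 25), a spread that keeps the
  whole distribution on the positive CtS axis.
* Baselines `mu_b = max(1100 − delta/2, 650)` place both group means at
  implied Ct of roughly 15–40 cycles; they are config fields, not
  hard-coded.
* Positivity: CtS is strictly positive, so profile rows containing a
  non-positive draw are redrawn (probability < 0.1% per patient at
  defaults), and replicate noise that would push a cycle count below zero
  is redrawn likewise. Both are bias-negligible at the default
  parameters and are exactly reproducible under a seed.
* The benign-vs-cancer scheme (202 cancer / 191 benign) reuses the same
  machinery with deltas 0.6 × the stratification deltas; no published
  effect sizes exist for that comparison, so these defaults are
  explicitly arbitrary plumbing.
* Synthetic PSA and Gleason covariates are attached for pipeline and
  subgroup bookkeeping only; they are drawn independently of the risk
  group and carry no calibrated association.

**What it does not emulate — and what passing tests therefore do not
show.** An important consequence of the bounded Ct-ratio scale: published
mean differences of ~1000 on a scale whose plausible width is ~1000,
*together with* the published merely-moderate p-values, imply within-group
spreads far larger than the positive scale can hold under any Gaussian
model. The generator prioritises the published mean differences and
positivity; as a result its default per-gene effect sizes (in SD units)
are much larger than the real assay's, and the simulated panel separates
the groups essentially perfectly (resubstitution AUC ≈ 1.0, versus ≈ 0.9
reported on real cohorts). Passing the calibration and pipeline tests
shows the machinery is correct and the generator hits its configured
moments — it does not show the panel would achieve any particular accuracy
on real urine samples. Real data will also feature skewed, heteroscedastic
expression, correlated genes, failed wells, censored Ct at the cycle
limit and preamplification bias; none of these are modelled.

## Numerical choices and degenerate inputs

* Covariance inversion is via Cholesky; a failed or near-zero-pivot
  factorization raises an error that names the class and suggests
  increasing `shrinkage` (pure QDA with fewer samples than genes is
  singular by construction).
* The polynomial and log-density scoring routes are kept as genuinely
  separate code paths so their agreement is an informative invariant, not
  a tautology.
* Exchangeable correlation $\rho$ must satisfy $-1/(p-1) < \rho < 1$ for
  positive definiteness; violations are reported with the offending value.
* Zero-variance genes make the t-test undefined and error explicitly;
  one-class inputs to ROC or confusion error rather than returning NaN;
  a degenerate caller (all calls one class) yields an `NA` metric where
  the denominator is empty rather than an error, since the remaining
  metrics are still well defined.
* Determinism: every stochastic step (simulation, noise, fold assignment)
  runs under an explicit seed; identical configurations produce
  byte-identical written reports.

## Evaluation problem sizes

The test suite and acceptance script size their simulations as follows:
calibration recovery uses 10,000 patients per group (standard error of a
recovered mean difference ≈ 2.8 on the ×1,000 scale, comfortably inside
the ±1% check on the largest delta); the null control uses 2,000 per
group; property suites use dozens of small random instances under fixed
seeds. These sizes make Monte-Carlo error negligible relative to every
tolerance tested while keeping a full run in the order of seconds.

## The null control and resubstitution optimism

With all deltas zero the panel carries no signal, and a sound pipeline
must report chance-level discrimination. This is evaluated *out of fold*
(stratified 5-fold, pooled out-of-fold scores), where the null AUC sits
at ≈ 0.50. It is deliberately not evaluated by resubstitution: a quadratic
discriminant over 14 genes estimates ~120 free parameters per class, and
even at 2,000 samples per group its resubstitution null AUC is ≈ 0.59 —
an intrinsic property of the estimator (the independent QDA implementation
used as an oracle gives the identical value), not an implementation
artifact. The same caveat applies to the headline resubstitution metrics
on any cohort: they carry optimism, which is why the k-fold protocol
exists and why reports label the protocol used.

## Known limitations

* The original assay's fitted coefficients were never published; this
  package reproduces the *printed functional form* and fits coefficients
  from data. Numeric identity with the original scores is impossible and
  out of scope.
* Real-data AUCs (~0.85–0.92) are not reproducible without the unpublished
  patient-level cohorts; the package reproduces every count-derivable
  published metric instead, exactly.
* Unclipped Wald intervals are a reproduction choice, not a
  recommendation; near p = 0 or 1 they undercover badly.
* The generator's Gaussian-on-CtS model is a deliberate simplification;
  see above for what that implies about transferring simulated
  performance to real cohorts.
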
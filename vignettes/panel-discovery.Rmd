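---
title: "Methods: minimal methylation panel discovery with methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimal methylation panel discovery with methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `methpanel`, the
reasoning for each default, and the scope and limits of the synthetic
cohort generator. It states methods, not results: empirical behavior is
established by the package's test suite and the acceptance script, and
nothing beyond what those compute is claimed here.

## 1. Scales and the classifier

Methylation fractions (β-values) live in (0,1) with variance that
depends on the mean. All modeling is done on M-values,
$M = \log_2\{\beta/(1-\beta)\}$ (`beta_to_m()`), which are
approximately Gaussian and homoscedastic.

The classifier is elastic-net logistic regression:
$$\min_{\beta_0,\beta}\ \tfrac1n\sum_i \ell(y_i, \beta_0 + x_i^\top\beta)
  \;+\; \lambda\Big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}2\|\beta\|_2^2\Big),$$
fit by `glmnet` on a design the package standardizes itself. Two
choices matter:

* **Frozen standardization.** The training means and SDs are stored in
  the model object and reused at prediction time. A panel exported as
  JSON (`write_panel_model()`) therefore applies to a replication
  cohort exactly as trained; re-standardizing per cohort would silently
  absorb distribution shift and is a common replication bug.
* **Ridge-leaning defaults for ranking.** When the goal is feature
  *ranking* rather than sparse prediction, a small α (we use 0.1)
  is preferable: causal CpGs in one regulatory region are mutually
  correlated, and lasso-dominant fits keep one member of a correlated
  group and zero the rest, destroying the rank consistency the rank
  product relies on. The ridge component spreads weight across the
  group so all members rank highly in every run.

## 2. Cross-validation engine

Evaluation uses r × stratified k-fold cross-validation (defaults
k = 10, r = 10). Within each training fold the minority class is
upsampled with replacement to balance; held-out folds never enter
upsampling, standardization, or tuning. Hyperparameters can be tuned
per outer run by an inner-CV grid search on ROC AUC
(`tuning = "nested"`); ties are broken toward the strongest penalty,
which keeps the procedure honest on uninformative data — under a label
permutation the best defensible model is the constant one, and the
tie-break lets the search collapse to it instead of chasing noise.

A `make_fold_plan()` object can be shared across models so that their
k·r per-run metrics are paired. This pairing is required by the
corrected test below.

## 3. Corrected repeated-CV test and the stopping rule

Per-run CV metrics are not independent: training sets overlap heavily
across runs, so the naive paired t-test on per-run differences is
anti-conservative. `corrected_cv_ttest()` uses the variance-corrected
statistic
$$t = \frac{\bar d}{\sqrt{\big(\tfrac1{kr} + \tfrac{n_2}{n_1}\big)\hat\sigma^2}},
\qquad \mathrm{df} = kr-1,$$
with $n_2/n_1 = 1/(k-1)$ for k-fold designs. Equivalently,
$|t| = |t_{\text{naive}}|/\sqrt{1 + kr/(k-1)}$: the correction factor
does **not** shrink as repeats accumulate, which is the point — extra
repeats reuse the same n samples and cannot manufacture evidence.

`incremental_selection()` grows the panel along the rank-product order
and tests each size-(s+1) panel against the size-s panel on a shared
fold plan. Growth continues while additions still help significantly
(p < `stop_alpha`) and stops at the first non-significant increment;
the selected size is the panel just before that increment. The full
path is always returned so the stopping decision is auditable. Note
the direction this implies: a looser `stop_alpha` keeps adding features
for longer, and `stop_alpha = 1` never stops before `max_size`.

For the *selection* CV we default to fixed hyperparameters rather than
nested tuning: the quantity under test is a paired difference between
two nested panels, and per-run tuning adds variance to both arms that
the correction then treats as real disagreement.

## 4. Metrics under class imbalance

ROC AUC is computed by the Mann–Whitney rank identity (tied pairs count
1/2). PRC AUC is tie-aware step-wise average precision with no
interpolation, since interpolated precision is optimistic. Its chance
level equals the positive-class prevalence — for an imbalanced cohort
this, not 0.5, is the number a panel must beat, and
`scripts/acceptance.R` recomputes that baseline by Monte Carlo.

## 5. The synthetic cohort generator

`simulate_cohort()` draws status first, then features conditional on
status. The default problem size — 348 children at prevalence 0.193,
134 nasal and 219 blood candidate CpGs, 101 SNPs plus a polygenic risk
score, 3 causal CpGs with standardized shift δ = 1.1 at pairwise
correlation ρ = 0.5, blood attenuation 0.1 — is this package's own
choice of a realistic, hard-but-feasible regime for a pediatric
methylation panel study; nothing in the code depends on these numbers
and every one is a `sim_config()` argument.

Generator structure worth knowing:

* Cases are IgE-sensitized with ≥1 symptom by construction
  (`omics_cohort()` enforces this logic on any input cohort).
* Causal CpG shifts are centred so that the marginal case–control
  difference is exactly δ even though cases carry a symptom-count
  gradient and IgE-positive controls a small shift of their own.
* Under equicorrelation, a p-CpG panel's analytic ceiling is
  $\Phi\!\big(\delta\sqrt{p/(1+(p-1)\rho)}/\sqrt2\big)$; ρ = 0.5 makes
  the second and third CpG worth little individually — deliberately,
  because that is the regime in which parsimony selection is
  interesting. Whether 0.5 is the right value for real co-regulated
  CpGs is an open modeling question; it is a single parameter to vary.
* SNP dosages are Hardy–Weinberg draws tilted class-conditionally by
  their log-odds effects; environmental binaries likewise. Expression
  (`simulate_expression()`) adds planted eQTM slopes over per-gene
  covariate and batch effects, leaving all other genes as calibration
  nulls. `simulate_mediation_chain()` produces a single-locus
  SNP → CpG → disease chain whose product-of-coefficients mediated
  proportion $ab/(ab + c')$ is known exactly.

Limits: the generator is class-conditional, not mechanistic — it plants
the marginal structure the pipeline is designed to detect (shifts,
correlations, slopes) and nothing else. There is no linkage
disequilibrium between SNPs, no cell-type composition confounding, no
missing data, and methylation noise is Gaussian on the M-scale with
unit variance. Conclusions about the *pipeline* transfer; conclusions
about biology do not.

## 6. Downstream interpretation

* `eqtm_scan()` / `meqtl_scan()`: vectorized QR-based OLS per pair;
  eQTM q-values are BH-adjusted within each CpG's gene family, so FDR
  is controlled per CpG, not experiment-wide. MeQTL flags are nominal
  (p < 0.05), appropriate for small candidate-SNP designs.
* `group_contrast()`: classical pooled-variance t contrasts with tier
  labels, for severity-gradient and sensitization-strata comparisons.
* `mediation_analysis()`: quasi-Bayesian counterfactual algorithm — the
  mediator and outcome models' coefficients are drawn from their
  asymptotic normals; potential mediators are simulated with a shared
  residual draw; ACME and ADE are risk differences averaged over both
  exposure arms. Without an exposure–mediator interaction,
  ACME + ADE = total within every draw, so the decomposition is exact
  and `additivity_gap` is a numerical-zero check. Intervals are
  percentile intervals over draws.

## 7. Numerical choices

* JSON model files store coefficients with 17 significant digits so a
  reloaded panel reproduces predictions bit-for-bit.
* `glmnet` is called with a padded zero column (excluded from the
  penalty) when a panel has a single feature, since the solver requires
  two columns; the pad cannot receive weight.
* All randomness flows from user-supplied integer seeds through
  explicit child seeds per repeat and per run; identical configurations
  give bit-identical cohorts, CV runs and pipeline artifacts.
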
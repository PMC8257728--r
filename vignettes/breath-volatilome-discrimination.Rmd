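---
title: "Discriminating asthma with coexisting atopy from the exhaled-breath volatilome"
author: "breathdiscrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating asthma with coexisting atopy from the exhaled-breath volatilome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathdiscrim)
```

## The problem

Thermal-desorption GC/MS of exhaled breath yields a table of relative
intensities for hundreds of *features* — ion peaks defined by a retention
time and a characteristic m/z — per subject. The scientific question served
by this package is whether that volatilome separates women with asthma and
coexisting atopic disease (A-AD) from non-asthmatic women with (NA-AD) or
without (NA-NAD) atopic disease, in a way that survives honest performance
estimation: cross-validation on a training cohort and a held-out,
date-separated validation cohort.

Three nuisance structures stand between the raw table and that question:

1. **Exogenous compounds.** Room air, gas-sampling bags (N,N-dimethyl-
   acetamide, phenol), pump oils and GC column siloxanes contribute
   features that have nothing to do with the subject.
2. **Batch variation.** Sampling season and the subject's residence zone
   (an air-quality-derived categorical label) shift many features at once.
3. **High dimension, few cases.** Far more features than cases, so an
   unregularized classifier overfits and an unvalidated AUC flatters.

The pipeline answers each in turn: *hyper-filtering* against paired room-air
samples, *ANOVA-simultaneous component analysis* (ASCA) to remove the
design-factor variation, and *L1-penalized logistic regression* (LASSO + LR)
with fivefold cross-validated penalty selection, permutation-test
significance, and external validation.

## Hyper-filtering against ambient air

Every breath sample is paired (by `pair_key`) with a room-air sample
collected at the same visit. After removing features annotated as
contaminants (`contaminant_class` in the feature metadata — matching is by
annotation, not by compound-name strings), each remaining feature is tested
with a one-sided paired Wilcoxon signed-rank test for *higher intensity in
ambient air than in breath*, on non-normalized intensities. Features with
p < `alpha` (default 0.05) are removed; the survivors are the
*hyper-filtered* features.

The signed-rank test drops zero differences, assigns mid-ranks to tied
absolute differences, and computes the tail probability **exactly** — by a
generating-function convolution over the (doubled) observed mid-ranks —
whenever at most 25 non-zero differences remain; beyond that it uses the
normal approximation with tie correction and a 0.5 continuity correction.
The exact path is checked in the test suite against brute-force enumeration
of all sign assignments.

Two deliberate defaults, both exposed as arguments:

* **No multiplicity correction** (`p_adjust = "none"`). The screen is meant
  to be aggressive towards exogenous features; a Benjamini–Hochberg option
  is available. Under `"none"` the screen is idempotent; under `"BH"` a
  second pass could in principle remove more (the adjusted p-values depend
  on the candidate set size).
* **Direction.** Only *ambient > breath* removes a feature. A feature
  elevated in breath relative to room air is evidence of endogenous origin
  and is kept regardless of significance.

## ASCA: removing season and zone variation

`asca_decompose()` column-centers the training matrix and partitions it
sequentially: for each factor, in the stated order (season, then zone), the
factor's effect matrix is the matrix of level means of the *current
remainder*, and is subtracted from it. The final remainder is the residual
matrix E used for modeling. Properties maintained and tested:

* exact reconstruction, `centered X = sum of effects + E`, balanced or not;
* under a balanced design, order invariance and additive sums of squares;
* each effect matrix is constant within a factor level.

The sequential level-means partition was chosen over a full ANOVA projection
because it keeps the reconstruction identity exact under arbitrary
unbalance, at the price of order dependence (the order is part of the model
statement). Effect matrices and E can be scored by `sca_effect()` (SVD:
scores = left singular vectors x singular values, orthonormal loadings),
and `asca_permutation_factor_test()` provides an add-one permutation p-value
for a factor's sum of squares. `pca_explore()` is the same decomposition
applied to the centered data matrix, for the initial exploratory look.

Two leakage rules are enforced by `run_comparison()`:

* ASCA is fitted on **training samples only**; validation samples are
  corrected with `residualize()` using the stored training level means. A
  validation sample from an unseen level gets the grand-mean-only fallback
  for that factor (with a warning).
* The hyper-filter's feature set is likewise determined on the training
  pairs by default (`filter_scope = "train"`); `"all"` is available because
  a screen applied before splitting is also a defensible design, and the
  difference is worth quantifying.

A dedicated test permutes validation-set labels and asserts that only the
validation metrics change.

Intensities enter ASCA untransformed by default; modeling is on the
residualized intensity scale. (The generator plants effects on the log10
scale, so the raw-scale level-mean removal is exact on the training set by
construction but only approximate in distribution — a realistic mismatch.)

## LASSO + logistic regression

The classifier minimizes `-(1/n) loglik + lambda * ||beta||_1` with an
unpenalized intercept. Variables are standardized to population mean 0 /
sd 1 at fit time (binary covariates included, so the penalty treats all
variables uniformly); coefficients are back-transformed, and odds ratios are
`exp(beta)` per unit of the original variable.

The solver is iteratively reweighted least squares with cyclic coordinate
descent and soft-thresholding on the working response, warm-started along a
decreasing penalty path, with an active-set Newton refinement: once a sweep
has stabilized the active set and signs, the constrained quadratic is solved
exactly and accepted only if it lowers the surrogate objective. A penalty is
declared converged only when the Karush–Kuhn–Tucker conditions hold at the
**true** gradient: `|grad_j| <= lambda` where `beta_j = 0` and
`grad_j = -lambda sign(beta_j)` elsewhere. `check_kkt()` recomputes the
residual for any fit; the suite asserts it on every converged fit and
cross-checks coefficients against an independent implementation (glmnet) and
against the unpenalized maximum-likelihood fit at `lambda = 0`.

Numerical choices (all arguments, defaults stated):

* coefficient-change tolerance `tol = 1e-7`; `max_iter = 1e5` sweeps;
* KKT tolerance `1e-6` for reported fits; the many path fits inside
  cross-validation accept `1e-4` — comfortably below anything that moves a
  deviance comparison or an AUC;
* the surrogate is solved to an adaptive inner tolerance (a tenth of the
  current KKT residual, floored at `tol`), which avoids polishing the
  weighted least-squares subproblem far beyond what the outer step needs;
* penalty grid: 20 points, log-spaced from `lambda_max` (the smallest
  all-zero penalty, `max_j |x_j'(y - ybar)|/n`) down to `lambda_max/1000`;
* `cv_select_lambda()` picks the grid minimizer of the cross-validated
  binomial deviance over stratified fivefold splits (an AUC criterion is
  available); ties go to the larger penalty. No 1-SE rule by default.

## Performance estimation

`cross_validated_auc()` is deliberately expensive: within each of the k
outer stratified folds the *entire* model building — nested fivefold penalty
selection included — is redone on the fold's training portion, and the AUC
(tie-corrected concordance, identical to the trapezoidal ROC area) is taken
on the held-out fold. `AUC_CV` is the plain mean of the fold AUCs.

`permutation_model_test()` permutes the labels and **rebuilds everything**
per permutation, because a frozen penalty would leak the observed labels
into the null statistic and bias the p-value downward. The p-value uses the
add-one rule `(1 + #(null >= observed)) / (1 + B)`, so its minimum at
B = 1000 is about 0.001. A labeled-approximate `fast = TRUE` mode freezes
the penalty for exploratory use.

Classification uses a prevalence cutoff — the training-set case proportion —
with ties at the cutoff going to case; validation sensitivity and
specificity are reported as integer percentages (half-up), the convention of
the accuracy tables this mirrors. `external_validation()` evaluates the
final training-set model (fitted at the cross-validated penalty) on the
residualized validation samples.

`default_catalog()` encodes the 16 standard comparisons: seven A-AD vs NA
models (VOCs alone and augmented with parental atopic history, blood
eosinophil count, other-atopic-disorder flags, and their combinations), four
A-AD vs NA-NAD and four A-AD vs NA-AD models (VOCs, +parental history,
+WBC counts, +both), and one VOC-only NA-AD vs NA-NAD model. WBC counts
enter raw (counts per µl) and are standardized inside the fit.

## The synthetic cohort generator

No raw cohort measurements are distributable, so `generate_cohort()` makes
the statistical structure the pipeline assumes:

* lognormal intensities — per-feature log10 baselines U(4, 6) with additive
  class, season, zone and noise effects on the log10 scale (GC/MS relative
  intensities behave multiplicatively);
* planted discriminant features: `effect_log2` log2-fold mean shift in
  cases (2.0 on the strong benchmark, i.e. a 4x intensity shift, about two
  log-scale noise SDs at the default `noise_sd_log = 0.3`);
* season and zone shifts drawn per (level, feature) with SDs 0.2 and 0.1 —
  batch effects comparable to or larger than many biological effects;
* a paired ambient sample per breath sample at `ambient_fraction = 0.2` of
  the breath baseline, sharing the visit's season/zone effects; planted
  ambient-dominant features at 10x that level; annotated contaminant
  features;
* clinical covariates drawn class-conditionally (parental history rates,
  atopy-flag rates consistent with the category definitions — NA-NAD
  carries no atopy flag — and WBC counts with a case shift in eosinophils),
  with all rates and shifts held in the configuration, not hard-coded;
* a stratified train/validation split; everything deterministic given one
  seed.

What the generator does **not** emulate: retention-time drift, peak-shape
and deconvolution artifacts, missingness, heavy-tailed or correlated
feature noise, and covariate–VOC dependence. Passing tests therefore
demonstrate that the machinery is correct and well calibrated under the
stated model, not that any particular clinical effect size is recoverable
in real breath data.

### Benchmark sizing

The full-scale generator defaults mirror the study cohort (39 cases, 297
controls, 300 features, a 125/336 validation fraction, so the training
split is about 25 cases vs 186 controls). The packaged **benchmark**
profiles (`benchmark_suite()`: null / moderate / strong, differing only in
planted effect) are reduced-scale cohorts: 20 cases vs 80 controls, 24
features, validation fraction 0.3. The reduction is deliberate: the
permutation-calibration suite rebuilds the entire cross-validated model
about 20,000 times (200 null cohorts x 100 rebuilds), and the recovery
suite another 400 times, and the statistical properties they check —
type-I calibration of the add-one permutation p-value, recovery of planted
discriminant features, operating characteristics of the ambient screen —
are portable across cohort size. At these sizes the whole suite runs on one
CPU in well under half an hour.

## Subject-characteristics statistics

`compare_continuous()` reproduces the gating logic of the cohort tables:
every group must pass *both* Shapiro–Wilk and Lilliefors tests at the gate
level for the parametric branch (t-test / one-way ANOVA); otherwise
Mann–Whitney U / Kruskal–Wallis. The AND-rule is the conservative reading
of "according to the data distribution"; groups too small for the
Lilliefors test (n < 4) cannot establish normality and default to the
nonparametric branch. `contingency_test()` uses Fisher's exact test
(two-sided by the point-probability rule) for 2x2 tables with any expected
cell below 5, and chi-square with Yates correction otherwise.
`subgroup_percentage()` rounds half-up to integer percent, the convention
under which the printed subgroup tables reproduce from their counts (the
shipped fixtures flag the one printed cell that is internally inconsistent
in the source tables).

## Worked example

```{r example, eval = FALSE}
library(breathdiscrim)

ch <- generate_cohort(benchmark_suite("strong")$strong)
spec <- comparison_spec("I.A", "A-AD", c("NA-AD", "NA-NAD"),
                        permutations = 199, seed = 1)
report <- run_comparison(spec, ch)
report
#> <model_report> I.A: A-AD vs NA-AD+NA-NAD
#>   AUC_CV 1.00  p 0.005  AUC_VS 0.99  sens 83%  spec 92%
#>   selected: F004, F008, F010, F012, F017, F018, F019, F022, F024
ch$truth$discriminant_ids   # the planted ground truth
#> [1] "F012" "F010" "F022"
```

## Known limitations

* The permutation test at full rebuild is computationally heavy by design;
  `B = 1000` on a full-scale cohort is an overnight computation on one CPU.
* ASCA's sequential partition is order-dependent on unbalanced data; the
  order (season, zone) is part of the model specification.
* The raw-intensity scale is heavy-tailed; an optional log10 transform
  before ASCA may be preferable for strongly skewed data and is left to the
  caller (`asca_decompose(log10(X), ...)`).
* Post-selection inference on the selected variables (confidence intervals
  for odds ratios after LASSO) is out of scope.
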
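---
title: "Predicting anticancer drug sensitivity from minimal mutation profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting anticancer drug sensitivity from minimal mutation profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oncoforest)
```

## The problem

High-throughput screens measure the concentration at which a compound
halves cancer-cell viability (IC50) across large panels of cell lines.
`oncoforest` models such screens with random forests, asking how far a
*minimal* genomic description — the binary mutation status of a panel of
oncogenes — combined with cheap 2-D chemical descriptors of the drug can
go in predicting (i) whether a compound is active against a cell line
(IC50 at or below a cutoff, conventionally 1 uM) and (ii) its
log10(IC50) value outright.

Every record is a (drug, cell line) pair.  Its feature vector joins the
cell line's mutation bits (1 = any sequence variation in that gene) with
a 1216-element chemical fingerprint of the drug: 192 continuous 2-D
descriptors followed by 1024 circular-fingerprint bits (radius 3, an
ECFP6 equivalent).  With the full 145-gene panel the vector has 1361
elements.

## Models and protocol

*Classification.* A ranger random forest (500 trees; `mtry =
round(sqrt(p))`, i.e. 37 at 1361 features) predicts active/inactive.
Performance is summarised by the confusion statistics — accuracy,
sensitivity, specificity, false positive rate, negative predictive value
— and Cohen's kappa `(p0 - pe)/(1 - pe)`, whose chance term uses the
marginal products `pe = ((TP+FN)(TP+FP) + (FP+TN)(FN+TN))/N^2`.
Undefined ratios (zero denominators) are reported as `NA` with a
warning, never silently coerced.

*Cross-validation.* Rows are shuffled under a recorded seed and split
into k contiguous folds (k = 5 by default); `ordered_folds = TRUE`
reproduces the historical "first 80% of rows" contiguous scheme, which
we do not default to because row order in an assembled matrix is an
artifact of join order.

*Class balancing.* When a cutoff makes the minority class rarer than
20%, SMOTE synthesises minority rows as convex combinations of a
minority point and one of its five minority nearest neighbours, and the
majority class is undersampled; both classes end at half the original
row count.  By default balancing happens inside each training fold
only, so synthetic points can never leak into a test fold;
`smote_before_split = TRUE` reproduces the cruder balance-then-split
protocol for comparison.

*ROC over activity cutoffs.* The screening ROC is traced by sweeping
the IC50 cutoff itself (45 values from 0.01 uM to 5000 uM), not by
thresholding a score: each cutoff is a fresh labeling, balanced if
needed, cross-validated, and contributes its mean (FPR, sensitivity)
point.  AUC is the trapezoid area over the FPR-sorted points plus the
(0,0) and (1,1) anchors.  Cutoffs whose labeling is single-class even
after balancing are skipped with a warning and simply omitted.

*Validation nulls.* y-randomization shuffles the labels of each
training split only; test folds keep true labels.  A pipeline free of
leakage and chance-correlation artifacts collapses to kappa near 0.
Leave-drugs-out validation withholds entire drugs (10 of the panel per
round by default) so the model is blind to the test chemistry —
the realistic scenario of a compound never screened before.

*Feature selection.* Genes are ranked by Gini (impurity) importance
from a forest on the full matrix.  Because absolute impurity magnitudes
are implementation-specific, all conclusions rest on ranks, not values.
The minimal-set search retains the top-N genes plus all chemical
descriptors and re-runs the CV for each N.  Per-drug analyses train on
each drug's rows using the gene columns only: within one drug every
chemical descriptor is constant, and constant columns cannot split a
tree — they only dilute the `mtry` candidate draw.  A gene is
*top-ranking* for a drug when its importance exceeds the drug's mean by
more than twice the population standard deviation (population rather
than sample: at 145 genes the distinction is negligible, and the
threshold is a population statement).

*Imputation.* Missing activity is simulated by masking 10-40% of
labels uniformly at random (MCAR — matching a deliberately random
removal process), then imputed by one of four methods: iterative
random-forest imputation (500 trees, at most 10 refit iterations —
with complete predictors the loop converges after the first pass),
kNN-9 majority vote, lasso-penalised logistic regression (penalty by
internal CV over a 100-step lambda path), or a CART classification
tree.  The binary activity class is imputed by default; the ambiguity
between imputing the class and imputing the continuous IC50 value is
real, and the regression-mode variants can be built from the same
primitives, but the classification reading is the one wired into
`imputation_experiment()`.  Downstream cost is measured by training on
imputed labels and evaluating only on rows whose labels were never
masked, so the evaluation target is always ground truth.

*Regression.* The same forests predict log10(IC50) directly, by
convention on the top-50 importance genes plus all 1216 descriptors.
Headline numbers are pooled over the concatenated out-of-fold
predictions (every row predicted exactly once); per-fold tables supply
dispersion.  Pearson/Spearman on constant vectors are undefined and
reported `NA`.

*Baselines.* Dummy classifiers (zero rule, stratified, uniform, kNN-9
majority) and dummy regressors (training mean, fixed quantile, kNN-9
mean), all under 10-fold CV, calibrate what "better than trivial"
means for each metric.

## Units and conventions

log(IC50) is stored as log10 of the molar concentration throughout (the
base is a convention we fix once; RMSE values are therefore in log10
units).  Cutoffs are quoted in micromolar and converted once at
labeling: 1 uM = 1e-6 M = -6 log10 units.  The activity comparison is
inclusive: IC50 equal to the cutoff is *active*.  Entropy-based gene
selection uses the binary entropy of the mutation frequency and breaks
ties lexicographically by gene id (the ordering is otherwise
undefined).

## The synthetic screen

Real screening releases cannot be bundled, so the package ships a
generative model (`ground_truth_model()`, `generate_dataset()`) whose
planted structure lets every downstream stage be validated by signal
recovery:

\[
y(d,c) = \mu + \alpha_d + \beta_c +
  \sum_{g,f} \gamma_{gf}\,\mathrm{mut}(c,g)\,\mathrm{fp}(d,f) +
  \varepsilon,\qquad \varepsilon \sim N(0,\sigma^2),
\]

clipped to the empirical screening range of log10 IC50, [-10.3, -0.4]
(5e-11 M to 0.4 M).  Mutations are independent Bernoulli draws with
heterogeneous per-gene frequencies; fingerprints are independent
Bernoulli bits plus Gaussian descriptors; missingness is MCAR.

The desk-scale preset — 300 cell lines x 40 drugs x 145 genes (12,000
records), 10 causal genes, noise sd 0.5 — emulates the structure of a
~990 x ~225 screen at a size where full pipelines run in minutes on one
CPU.  Its variance decomposition is deliberately screen-like:

* drug-to-drug potency offsets dominate (sd 1.5 log10 units), as they
  do in real panels where compound potencies span many orders of
  magnitude;
* each causal gene interacts with 8 fingerprint bits (density 0.35) at
  effect size 0.25, the sign shared across a gene's coefficients — a
  mutation either sensitizes or desensitizes cells to a chemotype.
  This spreads the genomic signal over a redundant chemical
  neighbourhood, the way real chemotypes recur across many bits;
* cell-line offsets are small (sd 0.3) and, with the noise sd of 0.5,
  form a near-irreducible floor;
* the baseline is recentred by Monte Carlo (`plant_class_balance()`)
  so the expected active fraction at 1 uM is 0.5; the 0.1/10 uM
  cutoffs then sit at roughly 30%/70% active — moderate, realistic
  imbalance.

A second preset, `noise_floor_preset()`, exists for one purpose: on
dense interaction structure a square-root-`mtry` forest provably
under-fits (it captures roughly half the interaction variance however
the structure is arranged), so the distance between its regression RMSE
and the generative noise would conflate pipeline loss with model-class
bias.  The noise-floor preset keeps the scale and the noise sd but
makes the planted signal fully recoverable in principle (interaction
effect 0.1, cell offsets 0.15, potency offsets dominating); on it, the
pooled out-of-fold RMSE sits within 1.5x the generative noise sd and
measures the pipeline alone.

What the generator does *not* emulate: tumor-type population structure,
gene-gene epistasis, correlated fingerprint blocks, drug-class
clustering, informative missingness, and assay artifacts.  Tests that
pass on this generator demonstrate that the pipeline recovers known
signal under honest validation; they do not certify performance levels
on any real screen.

`plant_class_balance()` feasibility: clipping never changes the active
fraction while the cutoff lies strictly inside the clip bounds (values
clip toward the bounds, not across the cutoff), so the solver errors
only when the cutoff leaves the bounds, the Monte-Carlo achieved
fraction misses the target by more than 2 points, or more than half the
mass would clip — the "physically absurd" regime.

## Numerical choices

* Forest fits are bit-reproducible: one thread, explicit seeds; every
  stochastic consumer derives its own sub-seed from the master seed and
  a purpose label (FNV-1a), so adding an experiment never perturbs
  another's randomness.
* `mtry` follows `round(sqrt(p))` at every feature count rather than
  freezing the full-matrix value of 37 when the gene subset shrinks.
* Importance ties and entropy ties break lexicographically by id.
* kNN uses exact blockwise BLAS distances, not approximate search.
* The lasso imputer's "100 iterations" budget is realised as the
  100-step lambda path of the coordinate-descent solver; capping the
  solver's inner iterations at 100 would silently return non-converged
  coefficients.
* Serialized models embed a format version and the feature schema;
  loading an incompatible blob fails loudly.

## Problem sizes in the test suite

The statistical properties asserted in the tests (kappa collapse under
y-randomization, planted-gene recovery, SMOTE geometry, graceful
imputation degradation, noise-floor regression error, ROC separation)
are stable in forest size and fold count, so the suite runs them with
100-200 trees and 3 folds — most on the desk preset, the drug-blind
comparisons on a 150-cell x 30-drug panel, and the ROC sweep on a
9-cutoff subgrid spanning the full 0.01-5000 uM range — sizes chosen
so the whole suite completes comfortably on a single CPU.
The analysis scripts under `analysis/` run the same experiments at the
full 500-tree, 5-fold protocol and write their tables under `results/`.

## Known limitations

* Descriptor values are not numerically comparable to any specific
  cheminformatics toolkit's descriptor set; the contract is the count
  (192), 2-D inputs only, determinism, and the documented manifest.
* The circular fingerprint folds hashed atom environments without
  duplicate-environment pruning; with binary bits this only affects bit
  collision rates.
* Gini importance magnitudes are toolkit-specific; only ranks travel.
* The generator's independence assumptions (bits, genes, cells) make
  recovery *easier* than in correlated real data; leave-drugs-out and
  y-randomization results are the honest checks least affected by this.
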
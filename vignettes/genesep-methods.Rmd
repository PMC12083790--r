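---
title: "Methods: separability-filtered classification of expression profiles"
author: "genesep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separability-filtered classification of expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesep)
```

## The problem

Microarray expression studies routinely measure tens of thousands of gene
probes on a few dozen samples. In this `p >> n` regime most classifiers
overfit badly unless the feature set is first reduced. genesep implements a
filter approach: every gene receives a score computed independently of any
classifier, genes are ranked, and only the top `k` (default 25) enter the
model. The package targets five-class leukemia subtype prediction
(`Bone_Marrow_CD34`, `Bone_Marrow`, `AML`, `PB`, `PBSC_CD34`; 8/10/26/10/10
samples), but nothing in the code is specific to that design.

## The separability score

For one gene, write its values across the `n` samples as `a_1..a_n`,
partitioned into classes `C_1..C_c` with sizes `n_1..n_c`. The score is
built in three steps:

1. class means: `m_j = (1/n_j) * sum over a_k in C_j of a_k`;
2. within-class absolute deviations: `b_k = |a_k - m_j|` for `a_k` in `C_j`;
3. per-class maxima and their minimum:
   `d_j = max over C_j of b_k`, and the gene's score `d = min over j of d_j`.

Genes are sorted by `d` in **descending** order (ties broken by ascending
gene index, so results are reproducible) and the top `k` are kept.

Properties the test suite asserts: `d >= 0`; absolute homogeneity
`d(alpha * x) = |alpha| * d(x)`; invariance to permuting samples and to
adding a constant to all values of one class; `d = 0` exactly when the gene
is constant within every class.

Note what this statistic measures: `d` is large when *every* class shows a
large extreme deviation from its own mean, i.e. it is a within-class
dispersion quantity, not a between-class distance. Ranking descending
therefore prefers genes whose spread inside each class is large. On data
where discriminative genes carry both between-class mean shifts and larger
within-class variance than the background (the regime the synthetic
generator produces, and a common situation on raw-scale microarray
intensities, where expressed genes have larger absolute variance than
near-silent probes), this ranking puts the informative genes first. An
`ascending` option is exposed for sensitivity analysis.

## Where the score is computed: the standardization question

Standardization (per-gene z-scoring, population-sd convention by default)
is part of the pipeline, but *where* it happens matters more than usual
here. Because the score is absolutely homogeneous, scoring a z-scored gene
divides its raw score by the gene's total standard deviation. That turns
the ranking into a coefficient-of-variation-like quantity: a pure-noise
gene with small total variance z-scores to unit spread and then outranks a
strongly class-separated gene, whose between-class signal inflates the
denominator. On the generator's default design this inversion is complete —
after z-scoring, the planted genes' within-class spread is about `1/6`
while background genes sit near `1` — and the selection would consist of
background noise.

The package therefore defaults to:

* **selection on the matrix as loaded** (no per-gene rescaling first), and
* **standardization of the selected genes only**, fitted on training rows
  and applied to held-out rows, before classification.

`standardize_before_select = TRUE` restores the literal
standardize-everything-first order for fidelity experiments, and
`fit_on_all` / `select_on_all` allow the leakage-prone variants in which
test rows inform the transform or the selection. Defaults avoid leakage:
selection and standardization see training rows only, both in the holdout
split and inside every cross-validation fold (selection is re-fitted per
fold).

The separate `abs_transform` flag (absolute value after z-scoring) is off
by default: the absolute value the method genuinely needs is the
`|a_k - m_j|` step inside the score, and taking `|.|` before computing
class means would destroy the sign structure those means rely on.

## Classifiers

All five kinds share one fit/predict contract (`fit_classifier()`,
`predict()`); pipeline code never branches on the kind. Training is
deterministic given the data and the seed.

| kind | backing | defaults |
|---|---|---|
| `random_forest` | randomForest | 100 trees |
| `decision_tree` | rpart (Gini) | `minsplit` 20, `cp` 0.01, no pruning CV |
| `linear_onehot` | written here | minimum-norm least squares via SVD |
| `svm_pca` | e1071 + prcomp | RBF, cost 1, 95% variance PCA, one-vs-rest |
| `lstm` | written here | hidden 64, 100 epochs, Adam 1e-3, batch 8 |

Design notes:

* **`linear_onehot`** regresses a one-hot indicator matrix on the selected
  genes plus intercept and predicts by the argmax of the linear scores
  (ties to the lowest class code). The fit is the minimum-norm least-squares
  solution computed by SVD, so it remains defined when features outnumber
  samples. Its coefficients are checked against `lm.fit` on every test run.
  Least-squares-on-indicators is known to *mask* middle classes when class
  means are collinear — exactly the geometry the synthetic generator uses —
  so its accuracy on the synthetic task is poor by construction. This is a
  faithful property of the method, not a defect of the implementation; a
  `link = "logistic"` alternative (per-class binomial GLM, argmax) is
  provided and clearly labelled as a variant.
* **`svm_pca`** projects onto the principal components retaining 95% of the
  training variance, then trains one binary SVM per class and predicts by
  the argmax of the decision values. One-vs-rest is used deliberately;
  libsvm's decision-value orientation follows order of appearance in the
  training data, so the wrapper re-orients each machine from the decision
  column name.
* **`lstm`** is a single-layer LSTM with a dense softmax head,
  cross-entropy loss, and Adam, implemented in base R with full
  backpropagation through time (gate order input/forget/cell/output,
  uniform `1/sqrt(h)` init, forget-gate bias 1). Tabular feature vectors
  have no natural sequence order; the default presents one feature per
  timestep (sequence length = `k`, input dimension 1), which keeps the
  recurrence non-degenerate, with `input_mode = "single_step"` as the
  alternative. A non-finite loss aborts training with an error; the
  per-epoch loss/accuracy history is kept on the model object.
* Class imbalance (26 AML vs 8 CD34) is left unweighted by default.

## Evaluation

`make_split()` produces a stratified 60/40 holdout (per-class training
counts are `round(0.6 * n_j)`, clamped to leave at least one sample on each
side); `kfold()` builds stratified folds whose total sizes differ by at
most one (leftover samples go to the currently smallest folds).
`evaluate_predictions()` computes the `c x c` confusion matrix (rows =
true) and one-vs-rest TP/FP/FN/TN per class, from which precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, F1, and specificity `TN/(TN+FP)` are
derived; zero-denominator cases are defined as 0. Aggregation defaults to
support-weighted averaging (macro and micro available; micro precision =
micro recall = accuracy is asserted as an internal identity). Specificity
is reported alongside precision because the two are easy to conflate in
metric tables; the package always uses the standard definitions above.
Five-fold accuracy is computed on the pooled out-of-fold predictions.

## The synthetic generator

`simulate_expression()` emulates the study design the package targets:
64 samples in classes of 8/10/26/10/10, `p = 2000` genes by default (a
`p = 22283` full-scale option exists for performance runs; 2000 keeps the
whole suite inside seconds-to-minutes while leaving `p >> n` intact), 20
planted informative genes drawn without replacement. Background genes are
`N(0, 0.1^2)` independent of class; a planted gene in class `j` is
`N(j * 5, 1)`. Class means are placed on the line `j * delta` rather than
in random directions so that failures are interpretable and a single gene
suffices in principle for separation; the within-class sd of planted genes
(1.0) deliberately exceeds the background sd (0.1) so that the descending
within-class-spread ranking places them first. What the generator does
*not* model: probe-level heteroscedasticity, batch effects, correlated gene
blocks, or heavy-tailed intensity distributions of real microarrays — so a
pass on synthetic data demonstrates the machinery, not clinical validity.

Everything is seeded: one global seed fans out to the split, fold, and
per-model seeds through fixed offsets, so changing one stage's
stochasticity never perturbs another's, and a rerun with the same resolved
configuration writes byte-identical JSON reports (full-precision numbers,
no timestamps in the payload).

## Worked example

```{r example}
sim <- simulate_expression(sim_config(seed = 1))
res <- run_pipeline(sim$matrix, k = 25, seed = 42, kfold_k = 5,
                    verbose = FALSE)
res
```

```{r recovery}
sel <- separability(sim$matrix, k = 20)
mean(sel$selected %in% sim$informative)
```

## Problem sizes and numerical choices

The test suite and the acceptance script run the selector-oracle comparison
on 200 random instances (`n <= 20`, `m <= 50`, `c <= 4`), the
planted-recovery and selected-versus-random comparisons over 20 simulated
datasets each, and one full pipeline (all five classifiers, holdout plus
5-fold) on a 64 x 2000 dataset. Standardization treats zero-variance genes
as all-zeros rather than dividing by zero; PCA drops numerically-zero
variance components; score ties and argmax ties break toward the lowest
index deterministically; the selector-oracle comparison is exact in double
precision because both paths accumulate class means in the same order.

## Known limitations

* The descending within-class-spread ranking is only appropriate when
  informative genes carry more raw variance than background; on variance-
  normalized input it inverts (see above). The `direction` and
  `standardize_before_select` flags exist to probe exactly this.
* `linear_onehot` suffers class masking on collinear class-mean geometries.
* The LSTM treats an arbitrary gene ordering as a sequence; its good
  performance here shows capacity, not that gene order is meaningful.
* Printed feature lists from prior studies of the GSE9476 dataset are
  reproduced only through the optional, download-dependent fidelity
  experiment (`fidelity_gse9476()`), which reports — and does not assert —
  selection overlap, because the published preprocessing and index
  conventions are underdetermined.
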
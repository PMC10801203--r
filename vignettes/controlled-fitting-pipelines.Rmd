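---
title: "Controlled-fitting classification pipelines: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled-fitting classification pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Drug-sensitivity classification from expression profiles lives in the
small-n / large-p regime: tens to a few hundred labelled samples against
thousands of features, often with strong class imbalance. Two failure
modes dominate there. First, *leakage*: any preprocessing step that sees
test samples (resampling, normalization statistics, supervised feature
ranking) optimistically biases the final estimate. Second, *hidden
overfitting*: a hyperparameter search steered only by a validation score
happily returns models that memorize the training partition as long as
the validation number looks acceptable.

`drugsense` hard-codes a stage order that addresses the first problem
structurally, and a pair of composite scores that address the second:

1. load CSV, encode the binary label, replace missing cells with 0;
2. draw a stratified test partition (and a validation partition for the
   search) **before anything else**;
3. run the feature-selection chain on the training partition only;
4. resample the training partition only;
5. fit the normalizer on the (resampled) training partition only;
6. search hyperparameters against the validation partition;
7. refit on train ∪ validation with the winning configuration;
8. score the untouched test partition once, plus repeated stratified CV
   on training data for ROC-AUC / average-precision curves;
9. emit a self-contained prediction bundle.

The resampling API takes no test data by construction, so leak-freedom
is an interface property, not a discipline; the test suite additionally
asserts byte-identity of the test partition across seeded end-to-end
runs.

# The scoring model

Seven losses are computed per partition, each mapped to [0, 1]: Hamming
loss, negative likelihood ratio, false negative / discovery / omission /
positive rates, and the Brier score loss. Conventions, applied uniformly
and reported when triggered:

* a rate whose denominator is 0 is defined as 0 (e.g., FDR when nothing
  is predicted positive);
* NLR = FNR / (1 − FPR) is clipped to [0, 1], with NLR = 1 when
  FPR = 1, so a single unbounded metric cannot dominate the composite;
* the Brier loss uses the raw positive-class probabilities, making it
  the only member sensitive to calibration rather than thresholding.

With the train and test metric vectors in hand, `D` is the
root-mean-square train−test difference, `L` the root-mean-square test
loss, and the composite is

`NegLog2RMSL = -log2( sqrt( (D + 0.05) * L ) )`,

the negative log2 of the geometric mean of `(D + 0.05)` and `L`. The
0.05 offset keeps the product informative when `D = 0` (otherwise a
model with any tiny gap and huge loss could tie a gapless one). One
genuinely open rendering question is where the radical sits relative to
the log; we evaluate `-log2` of the *geometric mean*, which equals half
of `-log2((D + 0.05) * L)`. The two forms are strictly monotone in one
another, so model rankings — the only use the platform puts the score to
— are identical under either reading; the choice is isolated in
`composite_score()`.

The hyperparameter objectives are built on the kappa–MCC error,
`KME = 1 − sqrt(max(κ, 0) · max(MCC, 0))`. Kappa and MCC are clipped at
zero before the geometric mean: a negative product has no real root, and
a worse-than-chance model should saturate at the maximal error 1 rather
than oscillate. A degenerate confusion table (MCC denominator 0) treats
MCC as 0, again reported. The controlled-fitting objective is
`custom_score = KME_val · |KME_train − KME_val|`. Note its designed
degeneracy: it is 0 whenever train and validation errors are equal,
*regardless of magnitude* — a model that is equally bad on both scores
0. In practice the search population always contains configurations that
separate the terms, and the objective's value lies in steering away from
memorizers; the formula is implemented exactly as specified, without an
additive guard.

# Feature selection: method-level decisions

Several of the selection methods required choices the method names alone
do not pin down. All are configurable; the defaults are:

* **MedianMAD** keeps features whose MAD *strictly* exceeds the median
  MAD; when every MAD is equal the strict set is empty and all features
  are returned with a warning (dropping everything would abort chains on
  degenerate inputs for no benefit).
* **SelByPCA** defines "top components" as the smallest set explaining
  ≥ 90% of variance (configurable), then ranks features by their maximum
  absolute loading across that set.
* **RandomProjection** draws a sparse (Achlioptas-type) projection with
  density 1/sqrt(p) and ranks original features by their aggregate
  absolute projection weight — a data-independent, seed-deterministic
  screen.
* **SelByNMF** shifts the matrix by its minimum when negatives are
  present (log-expression can be negative), factorizes with
  multiplicative updates (200 iterations, seeded uniform init), scales
  basis columns to unit sum, and ranks features by their maximum basis
  weight.
* **RemoveHighCorrFeat** scans the upper triangle of |Pearson r| in
  input order and drops the *later* feature of an offending pair; the
  exhaustive post-condition (no surviving pair above the threshold) is
  asserted in tests.
* **ModelX** builds second-moment equicorrelated Gaussian knockoffs
  (with shrinkage toward the identity when the correlation matrix is
  near-singular, reported), uses the lasso coefficient-difference
  statistic `W_j = |β_j| − |β̃_j|` from a cross-validated binomial
  fit on the augmented matrix, and applies the knockoff+ threshold. Null
  simulations in the test suite confirm empirical FDR control at the
  target within Monte-Carlo error.
* **IterativeFeatSel** enumerates every subset of size 1–3 and scores it
  by stratified-CV KME of a k-nearest-neighbour classifier (k = 5,
  3 folds). kNN, not a linear scorer, so jointly-informative (XOR-like)
  pairs are discoverable; ties break toward smaller subsets then feature
  order. The enumeration errors above a 50-feature cap for size-3
  searches — the intended use is as the last step of a reducing chain.
* Supervised forest methods use `ranger` impurity importance;
  RecursiveFeatElim refits after dropping the lowest-importance feature
  (step size configurable) and SeqFeatSel greedily grows the set under
  the shared CV scorer.

Chains are limited to four steps; each step sees only the survivors of
the previous one, provenance (method, in/out counts) is recorded, and an
empty survivor set aborts with the step named.

# The model registry

The 15 algorithm names map onto four categories. Because the task is
binary classification, the Ridge / Lasso / ElasticNet entries are
penalized *logistic* classifiers (`glmnet`, fixed user-supplied lambda).
SVC and NuSVC (`e1071`) are fitted with Platt-style probability
calibration so Brier losses are computable; this costs an internal CV
per fit. AdaBoost is a compact SAMME implementation over `rpart` stumps
(margins mapped to probabilities with the usual logistic link
`p = 1/(1 + exp(−2F))`). The five gradient-boosting entries are distinct
configurations of a shared boosting engine (`xgboost`): exact-split
boosting, histogram boosting, the fully regularized configuration, a
leaf-wise/histogram variant (loss-guided growth with a leaf cap, the
geometry LightGBM popularized), and a depth-wise heavily L2-regularized
variant. RandomForest is `randomForest`, ExtraTrees is `ranger` with the
extremely-randomized split rule, MLPC is a single-hidden-layer `nnet`
with weight decay. TabNet requires a deep-learning backend that is an
optional extra; requesting it raises an explicit optional-dependency
error and the platform runs with the remaining 14.

The class-imbalance weight (majority/minority count ratio, computed by
the sampling stage under "none") is applied as the positive-class weight
where the backend exposes one (`scale_pos_weight`, `class.weights`,
`classwt`) and as per-sample weights otherwise; NuSVC supports neither
and is fitted unweighted.

Every fit happens under a derived seed, and seeded determinism
(identical predictions from identical seeds) is asserted in tests for
the backends that guarantee it; boosting with multi-threading is the
usual exception, avoided here by pinning `nthread = 1`.

# Hyperparameter search

Three engines share one trial evaluator: fit on train, score on
validation, record `KME_train`, `KME_validation`, and the objective. A
single held-out validation split (default 20% of the dataset, stratified)
is used rather than nested CV — the per-trial cost stays linear and the
comparison among objectives is unaffected; this is the main place where
a heavier design was deliberately traded away. Failed fits (e.g.,
infeasible `nu`) score +Inf and the study continues.

* **grid** discretizes numeric dimensions round-robin until the grid
  would exceed the budget and enumerates; categorical dimensions always
  enumerate fully (budget permitting).
* **bayes** is sequential model-based optimization with a
  squared-exponential Gaussian-process surrogate on the unit-scaled
  space (fixed length-scale 0.3, standardized objective) and
  expected-improvement acquisition over 256 random candidates.
* **tpe** is a tree-structured Parzen estimator: the best 25% of trials
  form the "good" density, candidates sampled around good points are
  scored by the per-dimension good/bad kernel-density log-ratio
  (bandwidth 0.2 in unit space).

Both stochastic engines start from `max(4, d + 1)` random trials and are
fully reproducible per seed. The default budget is 50 trials; the
examples and tests use 4–15 because the fixtures are small.

The shipped search spaces are this package's own compact defaults around
each algorithm's main capacity and regularization knobs (documented in
`default_search_space()`); they are deliberately bounded and meant to be
overridden per call, not a claim about any upstream tool's internals.

# Interpretation

* **Built-in** importance: gain for boosted trees, impurity decrease for
  forests, |coefficient| for penalized-linear models, alpha-weighted
  split importance for AdaBoost. Kernel SVMs and the MLP return an
  explicit `unsupported_importance` marker rather than an error.
* **Permutation** importance uses the mean drop in `1 − KME` (the
  platform's own selection currency; ROC-AUC available) over independent
  column permutations; per-feature SDs over repeats are retained so
  "indistinguishable from zero" is checkable.
* **SHAP**: boosted trees use exact per-path contributions on the logit
  scale (additivity to the margin holds to numerical precision);
  penalized-linear models use the closed form
  `β_j (x_j − mean(background))`; all other backends use kernel SHAP on
  the probability scale — sampled coalitions weighted by the Shapley
  kernel, with the additivity constraint eliminated algebraically so the
  identity `sum(φ) + baseline = f(x)` holds exactly by construction.
  The background is capped at 100 rows.
* **LIME** perturbs around the sample with Gaussian noise scaled by
  background SDs, weights by an RBF proximity kernel (width
  `0.75·sqrt(p)`), screens to the top-10 features by weighted
  correlation, fits a weighted ridge surrogate, and reports signed
  weights plus the surrogate's weighted R² as a local-fidelity check.

Prediction bundles embed the background summary, so explanation of new
samples requires no training data. Missing features at prediction time
are an error listing the names — silent zero-filling would collide with
the NaN→0 cleaning convention and corrupt predictions undetectably.

# The synthetic fixtures, and what passing tests do (not) show

The generator draws labels with exact class counts, then adds a
class-conditional mean shift of `effect_size · noise_sd` to a random
subset of features over i.i.d. Gaussian noise; optional equicorrelated
blocks exercise correlation pruning, and an overfit-prone split
(n = 60, p = 300, 3 informative features at effect 1.5, split 30/15/15)
exercises the controlled-fitting objective. Defaults — n = 200, p = 500,
5 informative features at effect 2, balanced classes — are the package's
standard study conditions, chosen as a realistic desk-scale abstraction
of a pharmacogenomic cohort (hundreds of samples, far more features,
a handful of strong markers).

This Gaussian mean-shift model matches the *shape* of log-transformed
expression data but none of its harder properties: no count-distribution
noise, no batch structure, no correlated informative features, no label
noise, and effects that are individually (not only jointly) detectable.
Passing the recovery, FDR, and evaluation checks therefore demonstrates
that the machinery is correct under its stated assumptions — not that
any particular real cohort is predictable.

Problem sizes used by the simulation-backed tests were chosen to keep
the full suite desk-scale: 20 seeded runs for recovery and leak-freedom
properties, 100 null replicates for knockoff FDR, 10 seeds for the
controlled-fitting comparison, and 1,000 randomized instances for the
scoring-core equivalence sweep.

# Known limitations

* Normalization is fitted *after* resampling (sample → normalize); the
  reverse order is defensible too, and the choice is documented here
  precisely because it is not forced by anything upstream.
* Standardization uses the population SD (divisor n), so a two-point
  column maps to exactly (−1, +1).
* The final model is refit on train ∪ validation; the evaluation
  report's train-side metrics are computed on that (un-resampled) union,
  so under active resampling the train metrics describe the original
  rows rather than the resampled set the model saw.
* `custom_score`'s equal-error degeneracy (see above) is inherent to the
  printed formula.
* Repeated-CV curves refit with the *selected* hyperparameters; they
  estimate the stability of that configuration, not of the whole search.
* No multi-class support, no imputation, no non-CSV inputs, no stacking
  or meta-learning — all deliberately out of scope.
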
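# drugsense

Interpretable, leak-free binary classification pipelines for tabular
pharmacogenomic data — e.g., predicting whether a sample is **sensitive**
or **resistant** to a drug from its log2-normalized expression profile.
The package is aimed at computational biologists who need a complete,
reproducible pipeline (feature selection → resampling → normalization →
hyperparameter search → evaluation → interpretation → deployment) rather
than a bare classifier, and who care about two failure modes that
dominate small-n / large-p cohorts: **information leakage** into the test
set and **overfitting** hidden by single-number validation metrics.

## The scoring core

Model quality is summarized by a composite of seven losses, each in
[0, 1]: Hamming loss (HL), negative likelihood ratio (NLR, clipped to
[0, 1]), false negative rate (FNR), false discovery rate (FDR), false
omission rate (FOR), false positive rate (FPR), and Brier score loss
(BSL). With `M^train` and `M^test` the seven-metric vectors,

    D = sqrt( (1/7) * sum_j (M_j^train - M_j^test)^2 )   # RMS train-test gap
    L = sqrt( (1/7) * sum_j (M_j^test)^2 )               # RMS test loss
    NegLog2RMSL = -log2( sqrt( (D + 0.05) * L ) )        # higher is better

so a model is rewarded simultaneously for a low test loss and for a
small train–test divergence.

Hyperparameter search minimizes one of three objectives on a held-out
validation partition: the Hamming loss, the **kappa–MCC error**

    KME = 1 - sqrt( max(kappa, 0) * max(MCC, 0) )

(one minus the geometric mean of Cohen's kappa and the Matthews
correlation coefficient, clipped at zero), or the **controlled-fitting
objective**

    custom_score = KME_validation * | KME_train - KME_validation |

which penalizes plain validation error *and* the train/validation gap
that signals over- or underfitting.

## What's inside

* **dataio** — CSV in/out, binary label encoding, NaN→0 cleaning (no
  imputation), stratified train/validation/test splitting with the test
  partition drawn before any preprocessing.
* **synthetic fixtures** — expression-like generators with known
  informative features, tunable imbalance, correlated blocks, and an
  overfit-prone small-n/large-p split, so every stage is testable with
  ground truth.
* **feature selection** — HVF, MedianMAD, SelByPCA, RandomProjection,
  SelByClustering, SelByNMF, SelectByRF, RecursiveFeatElim, SeqFeatSel,
  model-X knockoffs with FDR control (ModelX), correlation pruning at
  |r| > 0.9 (RemoveHighCorrFeat), exhaustive 1–3-feature search
  (IterativeFeatSel), chained up to four steps with provenance.
* **preprocessing** — min-max / z-score / no normalization (fit on
  training data only); undersampling, oversampling, SMOTE, or "none"
  with a class-imbalance weight forwarded to the fit.
* **model zoo** — 15 algorithms in four categories (penalized logistic
  Ridge/Lasso/ElasticNet; SVC/NuSVC with calibrated probabilities;
  AdaBoost, gradient/histogram boosting variants, XGBoost, random
  forest, extremely randomized trees; multi-layer perceptron; TabNet as
  an optional backend) behind one fit/predict-probability contract.
* **hpo** — grid, GP-based Bayesian, and TPE engines, seeded and
  deterministic, with failed fits scored +Inf rather than crashing.
* **evaluation & interpretation** — untouched-test-set metrics, repeated
  stratified CV ROC-AUC / average precision, built-in and permutation
  importance, SHAP (exact for tree/linear models) and LIME.
* **prediction bundles** — one-file artifacts (model + feature list +
  normalizer + background summary + metadata) for standalone scoring
  and explanation of new samples.

## Worked example

```r
library(drugsense)

gen <- make_classification_data(
  synth_spec(n_samples = 200, n_features = 300, n_informative = 5,
             class_balance = 0.35, effect_size = 2, seed = 7))

cfg <- run_config(
  data = gen$dataset, positive_label = "sensitive",
  chain = list(selection_step("HVF", k = 100, seed = 7),
               selection_step("SelectByRF", k = 10, seed = 7)),
  normalization = "minmax", sampling = "none", algorithm = "XGBoost",
  engine = "tpe", objective = "custom_score", trials = 10,
  folds = 5, repeats = 5, seed = 7)

out <- run_training(cfg)
print(out$report)
#> <evaluation_report>
#>   test confusion: tp=13 fp=0 tn=26 fn=1
#>   test metrics: hl=0.025 nlr=0.071 fnr=0.071 fdr=0.000 for=0.037 fpr=0.000 bsl=0.016
#>   D=0.0420 L=0.0422 NegLog2RMSL=4.0048
#>   CV ROC-AUC 0.997 +/- 0.006; CV avg precision 0.995 +/- 0.009
intersect(out$selection$selected, gen$informative)
#> [1] "gene_0061" "gene_0123" "gene_0290" "gene_0055" "gene_0062"
```

The chain reduced 300 features to 10 and recovered all 5 planted
informative genes; the tuned model misclassifies 1 of 40 held-out
samples (HL = 0.025), and the small RMS train–test gap (D = 0.042)
combined with the small RMS test loss (L = 0.042) yields
NegLog2RMSL ≈ 4.0. The fitted pipeline is returned as `out$bundle`,
which can be saved with `save_bundle()` and used for standalone
prediction via `predict_samples()` / `explain_samples()` or the CLI
(`inst/cli/drugsense.R` with `train`, `select-features`, and `predict`
subcommands).

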
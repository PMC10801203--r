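# Independent brute-force implementations of the scoring core, coded from
# the metric definitions with different primitives (explicit counting,
# e1071's kappa, the phi-coefficient identity for MCC). These are the
# oracles the package implementation is checked against; they never call
# package code.

oracle_counts <- function(y, pred) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (y[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (y[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (y[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_loss_metrics <- function(y, pred, prob) {
  cc <- oracle_counts(y, pred)
  n <- length(y)
  div <- function(a, b) if (b == 0) 0 else a / b
  fnr <- div(cc["fn"], cc["fn"] + cc["tp"])
  fpr <- div(cc["fp"], cc["fp"] + cc["tn"])
  nlr <- if (fpr == 1) 1 else min(1, max(0, fnr / (1 - fpr)))
  unname(c((cc["fp"] + cc["fn"]) / n, nlr, fnr,
           div(cc["fp"], cc["fp"] + cc["tp"]),
           div(cc["fn"], cc["fn"] + cc["tn"]), fpr,
           sum((prob - y)^2) / n))
}

# MCC equals the Pearson correlation of the two binary vectors (phi
# coefficient); kappa cross-checked through e1071.
oracle_mcc <- function(y, pred) {
  if (sd(y) == 0 || sd(pred) == 0) return(0)
  stats::cor(y, pred)
}

oracle_kappa <- function(y, pred) {
  tab <- table(factor(y, levels = c(0, 1)), factor(pred, levels = c(0, 1)))
  k <- e1071::classAgreement(tab)$kappa
  if (!is.finite(k)) 0 else k   # same 0-for-degenerate convention
}

oracle_kme <- function(y, pred) {
  1 - sqrt(max(oracle_kappa(y, pred), 0) * max(oracle_mcc(y, pred), 0))
}

oracle_composite <- function(train, test) {
  D <- sqrt(sum((train - test)^2) / 7)
  L <- sqrt(sum(test^2) / 7)
  c(D = D, L = L, nl = -log2(sqrt((D + 0.05) * L)))
}

# Random prediction instance used by the equivalence sweeps.
random_instance <- function(n) {
  y <- rbinom(n, 1, runif(1, 0.2, 0.8))
  prob <- runif(n)
  pred <- rbinom(n, 1, prob)
  list(y = y, pred = pred, prob = prob)
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# Shared small fixture for model-level tests.
fixture_split <- function(seed = 42, n = 150, p = 30, k = 3,
                          effect = 2.5) {
  gen <- make_classification_data(
    synth_spec(n_samples = n, n_features = p, n_informative = k,
               effect_size = effect, seed = seed))
  sp <- stratified_split(gen$dataset, 0.2, seed = seed + 1,
                         validation_fraction = 0.2)
  attr(sp, "informative") <- gen$informative
  sp
}
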
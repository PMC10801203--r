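# The composite scoring core: seven loss metrics, the RMS difference (D)
# and loss (L) summaries, NegLog2RMSL, the kappa-MCC error (KME), and the
# controlled-fitting objective custom_score.
#
# Conventions (documented; applied consistently everywhere):
#  * any rate with a zero denominator is defined as 0;
#  * NLR = FNR / (1 - FPR) is clipped to [0, 1] (NLR = 1 when 1 - FPR = 0)
#    so no single unbounded metric can dominate the RMS;
#  * kappa and MCC are clipped at 0 before their geometric mean, so
#    worse-than-chance models score KME = 1;
#  * D and L are root-mean-square quantities over the 7 metrics, and
#    NegLog2RMSL = -log2(sqrt((D + 0.05) * L)), the negative log2 of the
#    geometric mean of (D + 0.05) and L.

#' Binary confusion counts
#'
#' @param y_true,y_pred Equal-length 0/1 vectors; 1 is the positive class.
#' @return A list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  list(tp = sum(y_true == 1 & y_pred == 1),
       fp = sum(y_true == 0 & y_pred == 1),
       tn = sum(y_true == 0 & y_pred == 0),
       fn = sum(y_true == 1 & y_pred == 0))
}

safe_rate <- function(num, den) if (den == 0) 0 else num / den

#' Seven-metric loss vector
#'
#' Computes the seven losses combined by the composite score: Hamming loss
#' (HL), negative likelihood ratio (NLR, clipped to `[0,1]`), false
#' negative rate (FNR), false discovery rate (FDR), false omission rate
#' (FOR), false positive rate (FPR), and Brier score loss (BSL).
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param y_prob Predicted positive-class probabilities in `[0,1]`.
#' @return Named numeric vector of length 7
#'   (`hl, nlr, fnr, fdr, for, fpr, bsl`), each in `[0,1]`.
#' @export
loss_metrics <- function(y_true, y_pred, y_prob) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (any(y_prob < 0 | y_prob > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  cc <- confusion_counts(y_true, y_pred)
  n <- length(y_true)
  hl <- (cc$fp + cc$fn) / n
  fnr <- safe_rate(cc$fn, cc$fn + cc$tp)
  fpr <- safe_rate(cc$fp, cc$fp + cc$tn)
  fdr <- safe_rate(cc$fp, cc$fp + cc$tp)
  for_ <- safe_rate(cc$fn, cc$fn + cc$tn)
  nlr <- if (1 - fpr == 0) 1 else min(1, max(0, fnr / (1 - fpr)))
  bsl <- mean((y_prob - y_true)^2)
  c(hl = hl, nlr = nlr, fnr = fnr, fdr = fdr, `for` = for_, fpr = fpr,
    bsl = bsl)
}

#' Composite evaluation score (NegLog2RMSL)
#'
#' `D` is the root-mean-square of the train-test differences of the seven
#' metrics, `L` the root-mean-square of the test metrics, and
#' `NegLog2RMSL = -log2(sqrt((D + 0.05) * L))`. Higher is better; the score
#' rewards low test loss and a small train-test gap simultaneously.
#'
#' @param train,test Length-7 metric vectors from [loss_metrics()].
#' @return A list with fields `D`, `L`, `neglog2rmsl`.
#' @export
composite_score <- function(train, test) {
  if (length(train) != 7 || length(test) != 7) {
    stop("metric vectors must have length 7", call. = FALSE)
  }
  D <- sqrt(mean((train - test)^2))
  L <- sqrt(mean(test^2))
  list(D = D, L = L, neglog2rmsl = -log2(sqrt((D + 0.05) * L)))
}

#' Cohen's kappa for a binary confusion table
#' @param cc Confusion counts from [confusion_counts()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cc) {
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  po <- (cc$tp + cc$tn) / n
  pe <- ((cc$tp + cc$fp) * (cc$tp + cc$fn) +
           (cc$tn + cc$fn) * (cc$tn + cc$fp)) / n^2
  if (1 - pe == 0) return(0)
  (po - pe) / (1 - pe)
}

#' Matthews correlation coefficient for a binary confusion table
#' @param cc Confusion counts from [confusion_counts()].
#' @return MCC in `[-1, 1]`; 0 when the denominator is degenerate.
#' @export
matthews_mcc <- function(cc) {
  den2 <- (cc$tp + cc$fp) * (cc$tp + cc$fn) * (cc$tn + cc$fp) *
    (cc$tn + cc$fn)
  if (den2 == 0) {
    ds_log("MCC denominator degenerate; treating MCC as 0")
    return(0)
  }
  (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(den2)
}

#' Kappa-MCC error
#'
#' `KME = 1 - sqrt(max(kappa, 0) * max(MCC, 0))`: one minus the geometric
#' mean of the chance-corrected agreement (Cohen's kappa) and the Matthews
#' correlation coefficient, both clipped at 0. Perfect prediction gives 0;
#' chance-level or worse gives 1.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @return KME in `[0, 1]`.
#' @export
kappa_mcc_error <- function(y_true, y_pred) {
  cc <- confusion_counts(y_true, y_pred)
  k <- max(cohen_kappa(cc), 0)
  m <- max(matthews_mcc(cc), 0)
  1 - sqrt(k * m)
}

#' Controlled-fitting hyperparameter objective
#'
#' `custom_score = KME_test * |KME_train - KME_test|`: small when the
#' validation error is low AND close to the training error, penalizing
#' both plain misfit and the train/validation divergence that signals
#' over- or underfitting. Minimized during hyperparameter search.
#'
#' @param kme_train,kme_test KME values in `[0, 1]`.
#' @return Non-negative objective value (lower is better).
#' @export
custom_score <- function(kme_train, kme_test) {
  if (kme_train < 0 || kme_train > 1 || kme_test < 0 || kme_test > 1) {
    stop("KME inputs must lie in [0,1]", call. = FALSE)
  }
  kme_test * abs(kme_train - kme_test)
}

#' Min-max normalize a set of composite scores
#'
#' Used when comparing NegLog2RMSL across models or compounds; rank order
#' is preserved. A constant input maps to all 0.5.
#'
#' @param scores Numeric vector of at least 2 finite scores.
#' @return Values in `[0, 1]`.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    ds_log("normalize_scores: constant input, mapping to 0.5")
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}
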
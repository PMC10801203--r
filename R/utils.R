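# Internal helpers shared across modules: seeded RNG scoping, fold
# construction, ranking-based scores, and lightweight logging.

#' @importFrom stats rnorm runif sd var median mad cor prcomp kmeans
#'   quantile dnorm pnorm predict coef dist setNames
#' @importFrom utils head read.csv write.csv packageVersion combn
# Backend namespaces must load with the package so their S3 predict/coef
# methods are registered even in sessions that only ever load a bundle.
#' @importFrom glmnet glmnet
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train
#' @importFrom nnet nnet
#' @importFrom rpart rpart
#' @importFrom class knn
#' @importFrom pROC auc
NULL

ds_log <- function(...) {
  message("[drugsense] ", ...)
}

# Derive a child seed from a base seed and a small offset, staying inside
# 32-bit integer range so downstream set.seed() calls are portable.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629L)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin so fold class counts differ by at most one.
make_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Area under the ROC curve via pROC; returns NA for degenerate truth vectors.
roc_auc <- function(y_true, y_prob) {
  if (length(unique(y_true)) < 2) return(NA_real_)
  as.numeric(pROC::auc(response = y_true, predictor = y_prob,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

# Average precision (area under the precision-recall curve, step-wise
# interpolation as used for average_precision_score).
average_precision <- function(y_true, y_prob) {
  if (sum(y_true == 1) == 0) return(NA_real_)
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  tp <- cumsum(y == 1)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y == 1)
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
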
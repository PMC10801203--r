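# Final-model evaluation: test-set confusion/metric vectors, the composite
# score, and repeated stratified cross-validated ROC-AUC / average
# precision curves computed on the training partition only (the test set
# is scored exactly once and never refit on).

#' Evaluate a fitted model
#'
#' The test partition is scored once with the already-fitted model; the
#' cross-validation curves refit the same algorithm and hyperparameters on
#' stratified folds drawn exclusively from the training partition.
#'
#' @param model A fitted `ml_model` (as returned by a
#'   [build_model()] factory's `fit`).
#' @param split A `ds_split` with train and test partitions (features must
#'   match the model's).
#' @param folds,repeats Stratified CV design (default 5 x 5).
#' @param seed Integer seed for fold draws and refits.
#' @return An `evaluation_report` with `confusion`, `metric_vector_train`,
#'   `metric_vector_test`, `composite`, `roc_auc_cv`, `avg_precision_cv`
#'   (each mean/sd plus per-fold values).
#' @export
evaluate_model <- function(model, split, folds = 5, repeats = 5,
                           seed = 1) {
  stopifnot(inherits(model, "ml_model"), inherits(split, "ds_split"))
  if (nrow(split$test$X) == 0) stop("test partition is empty",
                                    call. = FALSE)
  feats <- model$feature_names
  X_tr <- split$train$X[, feats, drop = FALSE]
  X_te <- split$test$X[, feats, drop = FALSE]
  y_tr <- split$train$y; y_te <- split$test$y

  prob_te <- predict_prob(model, X_te)
  pred_te <- as.integer(prob_te >= 0.5)
  prob_tr <- predict_prob(model, X_tr)
  pred_tr <- as.integer(prob_tr >= 0.5)

  mv_test <- loss_metrics(y_te, pred_te, prob_te)
  mv_train <- loss_metrics(y_tr, pred_tr, prob_tr)
  comp <- composite_score(mv_train, mv_test)

  auc_folds <- c(); ap_folds <- c()
  for (r in seq_len(repeats)) {
    fold <- make_folds(y_tr, folds, child_seed(seed, 200L + r))
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y_tr[tr])) < 2 ||
          length(unique(y_tr[te])) < 2) next
      refit <- build_model(model_spec(model$name, model$hyperparameters),
                           class_weight = model$class_weight,
                           seed = child_seed(seed, 300L + r * folds + f)
      )$fit(X_tr[tr, , drop = FALSE], y_tr[tr])
      p <- predict_prob(refit, X_tr[te, , drop = FALSE])
      auc_folds <- c(auc_folds, roc_auc(y_tr[te], p))
      ap_folds <- c(ap_folds, average_precision(y_tr[te], p))
    }
  }
  structure(list(
    confusion = confusion_counts(y_te, pred_te),
    metric_vector_train = mv_train,
    metric_vector_test = mv_test,
    composite = comp,
    roc_auc_cv = list(mean = mean(auc_folds, na.rm = TRUE),
                      sd = sd(auc_folds), per_fold = auc_folds),
    avg_precision_cv = list(mean = mean(ap_folds, na.rm = TRUE),
                            sd = sd(ap_folds), per_fold = ap_folds),
    folds = folds, repeats = repeats, seed = as.integer(seed)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  test confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn,
              x$confusion$fn))
  cat("  test metrics:",
      paste(sprintf("%s=%.3f", names(x$metric_vector_test),
                    x$metric_vector_test), collapse = " "), "\n")
  cat(sprintf("  D=%.4f L=%.4f NegLog2RMSL=%.4f\n", x$composite$D,
              x$composite$L, x$composite$neglog2rmsl))
  cat(sprintf("  CV ROC-AUC %.3f +/- %.3f; CV avg precision %.3f +/- %.3f\n",
              x$roc_auc_cv$mean, x$roc_auc_cv$sd,
              x$avg_precision_cv$mean, x$avg_precision_cv$sd))
  invisible(x)
}
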
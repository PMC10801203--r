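# Model interpretation: built-in importances where the backend has them,
# permutation importance, SHAP attributions (exact TreeSHAP for boosted
# trees via the booster's contribution predictions, exact linear SHAP for
# penalized-linear models, constrained kernel SHAP otherwise), and LIME
# local surrogates.

#' Construct an attribution set
#'
#' @param scope `"global"` (one score per feature) or `"local"` (a matrix
#'   of per-sample, per-feature scores).
#' @param method The producing method (`"builtin"`, `"permutation"`,
#'   `"shap"`, `"lime"`).
#' @param scores Named numeric vector (global) or matrix with feature
#'   columns (local).
#' @param baseline Description or value of the reference the scores are
#'   relative to.
#' @param details Optional method-specific extras.
#' @return An `attribution_set` object.
#' @export
attribution_set <- function(scope, method, scores, baseline = NULL,
                            details = list()) {
  structure(list(scope = scope, method = method, scores = scores,
                 baseline = baseline, details = details),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("<attribution_set> %s %s\n", x$scope, x$method))
  s <- if (is.matrix(x$scores)) colMeans(abs(x$scores)) else abs(x$scores)
  top <- head(sort(s, decreasing = TRUE), 10)
  cat("  top features:",
      paste(sprintf("%s (%.3g)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Built-in (model-specific) feature importance
#'
#' Tree and boosting backends expose impurity/gain importance and
#' penalized-linear models expose absolute coefficients. Kernel SVMs and
#' the multi-layer perceptron have no intrinsic importance: for those an
#' `unsupported_importance` marker is returned (not an error), steering
#' callers to permutation or SHAP.
#'
#' @param model A fitted `ml_model`.
#' @return An `attribution_set` (global, method `"builtin"`), or an
#'   `unsupported_importance` object carrying the reason.
#' @export
builtin_importance <- function(model) {
  stopifnot(inherits(model, "ml_model"))
  feats <- model$feature_names
  scores <- switch(
    model$name,
    Ridge = ,
    Lasso = ,
    ElasticNet = {
      b <- abs(as.numeric(coef(model$fit))[-1])
      names(b) <- feats
      b
    },
    GradientBoosting = ,
    HistGradientBoosting = ,
    XGBoost = ,
    LightGBM = ,
    CatBoost = {
      imp <- xgboost::xgb.importance(model = model$fit$booster)
      out <- setNames(rep(0, length(feats)), feats)
      out[imp$Feature] <- imp$Gain
      out
    },
    RandomForest = {
      imp <- randomForest::importance(model$fit)[, 1]
      setNames(as.numeric(imp), feats)
    },
    ExtraTrees = setNames(as.numeric(model$fit$variable.importance),
                          feats),
    AdaBoost = {
      # aggregate rpart variable importance over the boosted stages
      agg <- setNames(rep(0, length(feats)), feats)
      for (m in seq_along(model$fit$stumps)) {
        vi <- model$fit$stumps[[m]]$variable.importance
        if (!is.null(vi)) {
          agg[names(vi)] <- agg[names(vi)] +
            model$fit$alphas[m] * as.numeric(vi)
        }
      }
      agg
    },
    NULL
  )
  if (is.null(scores)) {
    return(structure(
      list(reason = sprintf(
        "%s has no intrinsic importance; use permutation or SHAP",
        model$name)),
      class = "unsupported_importance"))
  }
  attribution_set("global", "builtin", scores)
}

#' Permutation feature importance
#'
#' Importance of a feature = mean drop in a base score across `n_repeats`
#' independent permutations of that feature's column in the held-out data.
#' The default base score is `1 - KME`, consistent with the platform's
#' model-selection criterion; `"roc_auc"` is available as an alternative.
#'
#' @param model A fitted `ml_model`.
#' @param X,y Held-out feature matrix and 0/1 labels.
#' @param n_repeats Permutations per feature (>= 1).
#' @param seed Integer seed; output is deterministic per seed.
#' @param base_score `"kme"` (default) or `"roc_auc"`.
#' @return An `attribution_set` (global, method `"permutation"`) whose
#'   `details$sd` carries per-feature SDs across repeats.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10, seed = 1,
                                   base_score = c("kme", "roc_auc")) {
  base_score <- match.arg(base_score)
  if (nrow(X) < 2) stop("need at least 2 held-out rows", call. = FALSE)
  score_fn <- function(Xs) {
    p <- predict_prob(model, Xs)
    if (base_score == "kme") 1 - kappa_mcc_error(y, as.integer(p >= 0.5))
    else roc_auc(y, p)
  }
  base <- score_fn(X)
  feats <- model$feature_names
  drops <- matrix(NA_real_, n_repeats, length(feats),
                  dimnames = list(NULL, feats))
  with_seed(seed, {
    for (j in seq_along(feats)) {
      for (r in seq_len(n_repeats)) {
        Xp <- X
        Xp[, feats[j]] <- X[sample.int(nrow(X)), feats[j]]
        drops[r, j] <- base - score_fn(Xp)
      }
    }
  })
  attribution_set("global", "permutation", colMeans(drops),
                  baseline = base,
                  details = list(sd = apply(drops, 2, sd),
                                 n_repeats = n_repeats))
}

#' SHAP attributions
#'
#' Local attributions are additive per-feature contributions such that
#' `sum(contributions) + baseline = model output` for each explained
#' sample (on the margin/logit scale for tree and linear models). Global
#' importance is the mean absolute local value per feature.
#'
#' Boosted-tree backends use exact tree-path contributions; penalized
#' linear models use the closed form `beta_j * (x_j - mean(background))`;
#' all other backends use a kernel SHAP estimate (weighted least squares
#' over sampled coalitions with the additivity constraint enforced).
#'
#' @param model A fitted `ml_model`.
#' @param X_background Background matrix defining the reference
#'   distribution (subsampled to at most 100 rows).
#' @param X_explain Samples to explain.
#' @param scope `"global"` or `"local"`.
#' @param n_coalitions Sampled coalitions for the kernel estimator.
#' @param seed Integer seed (kernel path only).
#' @return An `attribution_set`; local scores are a samples x features
#'   matrix with attribute `baseline`.
#' @export
shap_attribution <- function(model, X_background, X_explain,
                             scope = c("global", "local"),
                             n_coalitions = 128, seed = 1) {
  scope <- match.arg(scope)
  if (nrow(X_background) == 0) stop("background set is empty",
                                    call. = FALSE)
  feats <- model$feature_names
  X_background <- X_background[, feats, drop = FALSE]
  X_explain <- X_explain[, feats, drop = FALSE]
  if (nrow(X_background) > 100) {
    X_background <- X_background[
      with_seed(seed, sample.int(nrow(X_background), 100)), ,
      drop = FALSE]
  }
  tree_like <- model$name %in% c("GradientBoosting",
                                 "HistGradientBoosting", "XGBoost",
                                 "LightGBM", "CatBoost")
  linear_like <- model$name %in% c("Ridge", "Lasso", "ElasticNet")
  if (tree_like) {
    ctr <- predict(model$fit$booster, xgboost::xgb.DMatrix(X_explain),
                   predcontrib = TRUE)
    base <- ctr[1, ncol(ctr)]
    local <- ctr[, -ncol(ctr), drop = FALSE]
    colnames(local) <- feats
  } else if (linear_like) {
    b <- as.numeric(coef(model$fit))[-1]
    mu <- colMeans(X_background)
    local <- sweep(X_explain, 2, mu) %*% diag(b, length(b))
    colnames(local) <- feats
    base <- as.numeric(coef(model$fit))[1] + sum(b * mu)
  } else {
    local <- kernel_shap(model, X_background, X_explain,
                         n_coalitions = n_coalitions, seed = seed)
    base <- attr(local, "baseline")
  }
  if (scope == "local") {
    out <- attribution_set("local", "shap", local, baseline = base)
  } else {
    out <- attribution_set("global", "shap", colMeans(abs(local)),
                           baseline = base)
  }
  out
}

# Kernel SHAP on the probability scale: for each explained row, sample
# coalitions z in {0,1}^p (plus the all-off/all-on anchors), build hybrid
# samples from the background, and solve the Shapley-kernel-weighted least
# squares with the additivity constraint eliminated algebraically.
kernel_shap <- function(model, X_background, X_explain, n_coalitions,
                        seed) {
  p <- ncol(X_explain)
  nb <- nrow(X_background)
  f_base <- mean(predict_prob(model, X_background))
  local <- matrix(0, nrow(X_explain), p,
                  dimnames = list(rownames(X_explain),
                                  colnames(X_explain)))
  with_seed(seed, {
    for (i in seq_len(nrow(X_explain))) {
      x <- X_explain[i, ]
      f_x <- predict_prob(model, matrix(x, 1, p,
                                        dimnames = list(NULL, names(x))))
      m <- min(n_coalitions, max(16, 2 * p))
      sizes <- pmin(pmax(1, stats::rbinom(m, p - 2, 0.5) + 1), p - 1)
      Z <- t(vapply(sizes, function(s) {
        z <- rep(0, p); z[sample.int(p, s)] <- 1; z
      }, numeric(p)))
      ssum <- rowSums(Z)
      w <- (p - 1) / (choose(p, ssum) * ssum * (p - ssum))
      # evaluate each coalition against one background draw per coalition
      bg <- X_background[sample.int(nb, m, replace = TRUE), ,
                         drop = FALSE]
      hyb <- bg
      hyb[Z == 1] <- matrix(x, m, p, byrow = TRUE)[Z == 1]
      fz <- predict_prob(model, hyb)
      # eliminate the constraint sum(phi) = f_x - f_base
      delta <- f_x - f_base
      Zr <- Z[, -p, drop = FALSE] -
        matrix(Z[, p], m, p - 1)
      yr <- fz - f_base - Z[, p] * delta
      WZ <- Zr * w
      A <- crossprod(WZ, Zr) + diag(1e-8, p - 1)
      phi_r <- solve(A, crossprod(WZ, yr))
      phi <- c(phi_r, delta - sum(phi_r))
      local[i, ] <- phi
    }
  })
  attr(local, "baseline") <- f_base
  local
}

#' LIME local explanation
#'
#' Fits a proximity-weighted ridge surrogate to the model's probability
#' surface on Gaussian perturbations around one sample, after restricting
#' to the `top_k` features most correlated with the local predictions.
#' Reports signed surrogate weights and the surrogate's weighted R^2
#' (local fidelity).
#'
#' @param model A fitted `ml_model`.
#' @param sample A single named feature vector (or 1-row matrix).
#' @param X_background Matrix used to scale perturbations.
#' @param n_perturbations Number of perturbed samples (default 500).
#' @param seed Integer seed; explanations are deterministic per seed.
#' @param top_k Number of features retained in the surrogate.
#' @param kernel_width Proximity kernel width in scaled-distance units
#'   (default `0.75 * sqrt(p)`).
#' @return An `attribution_set` (local, method `"lime"`) with
#'   `details$r_squared`.
#' @export
lime_attribution <- function(model, sample, X_background,
                             n_perturbations = 500, seed = 1, top_k = 10,
                             kernel_width = NULL) {
  if (is.matrix(sample)) sample <- sample[1, ]
  feats <- model$feature_names
  sample <- sample[feats]
  p <- length(feats)
  sds <- apply(X_background[, feats, drop = FALSE], 2, sd)
  sds[sds == 0] <- 1
  kernel_width <- kernel_width %||% (0.75 * sqrt(p))
  with_seed(seed, {
    pert <- matrix(rnorm(n_perturbations * p), n_perturbations, p)
    Xp <- sweep(pert, 2, sds, "*") +
      matrix(sample, n_perturbations, p, byrow = TRUE)
    colnames(Xp) <- feats
    yp <- predict_prob(model, Xp)
    if (sd(yp) < 1e-10) {
      stop("degenerate perturbation response (constant model output)",
           call. = FALSE)
    }
    dist2 <- rowSums(pert^2)
    w <- exp(-dist2 / kernel_width^2)
    # feature screening by |weighted correlation| with the prediction
    Zs <- sweep(Xp, 2, sample)
    wc <- abs(vapply(seq_len(p), function(j) {
      stats::cov.wt(cbind(Zs[, j], yp), wt = w, cor = TRUE)$cor[1, 2]
    }, numeric(1)))
    wc[is.na(wc)] <- 0
    keep <- order(-wc)[seq_len(min(top_k, p))]
    Zk <- Zs[, keep, drop = FALSE]
    # weighted ridge on the retained features
    lam <- 1e-4
    A <- crossprod(Zk * w, Zk) + diag(lam, length(keep))
    b <- solve(A, crossprod(Zk * w, yp - mean(yp)))
    coef <- setNames(rep(0, p), feats)
    coef[keep] <- as.numeric(b)
    pred_surr <- mean(yp) + Zk %*% b
    ss_res <- sum(w * (yp - pred_surr)^2)
    ss_tot <- sum(w * (yp - sum(w * yp) / sum(w))^2)
    attribution_set("local", "lime", coef,
                    baseline = mean(yp),
                    details = list(r_squared = 1 - ss_res / ss_tot,
                                   kept = feats[keep]))
  })
}
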
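# The 15-algorithm registry, grouped into regularized-linear, SVM,
# ensemble, and neural-network categories, behind one uniform contract:
# build_model() returns a factory whose fit() yields an object supporting
# predict_prob() / predict_label(). The class-imbalance weight is applied
# as the positive-class weight where the backend supports it, and as
# per-sample weights otherwise.

ALGORITHMS <- c(Ridge = "regularized-linear", Lasso = "regularized-linear",
                ElasticNet = "regularized-linear", SVC = "svm",
                NuSVC = "svm", AdaBoost = "ensemble",
                GradientBoosting = "ensemble",
                HistGradientBoosting = "ensemble", XGBoost = "ensemble",
                LightGBM = "ensemble", CatBoost = "ensemble",
                RandomForest = "ensemble", ExtraTrees = "ensemble",
                MLPC = "neural-network", TabNet = "neural-network")

#' List the registered algorithms
#' @return Named character vector: algorithm name -> category.
#' @export
list_algorithms <- function() ALGORITHMS

#' Describe a model to build
#'
#' @param name One of the 15 registered algorithm names.
#' @param hyperparameters Named list overriding the algorithm's defaults.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, hyperparameters = list()) {
  if (!name %in% names(ALGORITHMS)) {
    stop(sprintf("unknown algorithm '%s'; valid names: %s", name,
                 paste(names(ALGORITHMS), collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, category = ALGORITHMS[[name]],
                 hyperparameters = hyperparameters),
            class = "model_spec")
}

default_hyperparameters <- function(name) {
  switch(name,
    Ridge = list(lambda = 0.05),
    Lasso = list(lambda = 0.01),
    ElasticNet = list(lambda = 0.01, alpha = 0.5),
    SVC = list(cost = 1, gamma = NULL),
    NuSVC = list(nu = 0.3, gamma = NULL),
    AdaBoost = list(n_estimators = 50, learning_rate = 0.5, max_depth = 1),
    GradientBoosting = list(nrounds = 100, eta = 0.1, max_depth = 3,
                            subsample = 1),
    HistGradientBoosting = list(nrounds = 100, eta = 0.1, max_depth = 4,
                                subsample = 1),
    XGBoost = list(nrounds = 100, eta = 0.1, max_depth = 4,
                   subsample = 0.9, colsample = 0.9, reg_lambda = 1),
    LightGBM = list(nrounds = 100, eta = 0.1, max_leaves = 31,
                    subsample = 0.9, colsample = 0.9),
    CatBoost = list(nrounds = 150, eta = 0.08, max_depth = 6,
                    subsample = 0.9, reg_lambda = 3),
    RandomForest = list(num_trees = 300, mtry_frac = NULL, min_node = 1),
    ExtraTrees = list(num_trees = 300, mtry_frac = NULL, min_node = 1),
    MLPC = list(size = 8, decay = 0.01, maxit = 200),
    TabNet = list(n_steps = 3, width = 8),
    stop("unknown algorithm", call. = FALSE))
}

#' Build a model factory
#'
#' Returns a factory honoring the uniform contract: `$fit(X, y)` trains on
#' a numeric matrix and 0/1 labels and returns an `ml_model` supporting
#' [predict_prob()] and [predict_label()]. Regularized-linear names are
#' penalized logistic classifiers; SVMs expose Platt-calibrated
#' probabilities.
#'
#' @param spec A [model_spec()].
#' @param class_weight Positive-class weight (majority/minority ratio from
#'   the sampling stage; 1 = balanced).
#' @param seed Integer seed for stochastic backends.
#' @return A `model_factory` list with `fit`, `spec`, `class_weight`,
#'   `seed`.
#' @export
build_model <- function(spec, class_weight = 1, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$name == "TabNet") {
    stop(paste("TabNet requires an optional deep-learning backend that is",
               "not installed; the remaining 14 algorithms are available"),
         call. = FALSE)
  }
  hp <- utils::modifyList(default_hyperparameters(spec$name),
                          spec$hyperparameters)
  factory <- list(
    spec = spec, class_weight = class_weight, seed = as.integer(seed),
    fit = function(X, y) {
      fit_backend(spec$name, X, as.integer(y), hp, class_weight,
                  as.integer(seed))
    })
  class(factory) <- "model_factory"
  factory
}

fit_backend <- function(name, X, y, hp, cw, seed) {
  if (!is.matrix(X)) X <- as.matrix(X)
  w <- ifelse(y == 1, cw, 1)
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(seed, switch(
    name,
    Ridge = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                           lambda = hp$lambda, weights = w),
    Lasso = glmnet::glmnet(X, yf, family = "binomial", alpha = 1,
                           lambda = hp$lambda, weights = w),
    ElasticNet = glmnet::glmnet(X, yf, family = "binomial",
                                alpha = hp$alpha, lambda = hp$lambda,
                                weights = w),
    SVC = e1071::svm(X, yf, type = "C-classification", kernel = "radial",
                     cost = hp$cost, gamma = hp$gamma %||% (1 / ncol(X)),
                     probability = TRUE,
                     class.weights = c("0" = 1, "1" = cw)),
    NuSVC = e1071::svm(X, yf, type = "nu-classification",
                       kernel = "radial", nu = hp$nu,
                       gamma = hp$gamma %||% (1 / ncol(X)),
                       probability = TRUE),
    AdaBoost = fit_adaboost(X, y, hp, w),
    GradientBoosting = fit_xgb(X, y, cw, seed, nrounds = hp$nrounds,
                               eta = hp$eta, max_depth = hp$max_depth,
                               subsample = hp$subsample,
                               tree_method = "exact"),
    HistGradientBoosting = fit_xgb(X, y, cw, seed, nrounds = hp$nrounds,
                                   eta = hp$eta, max_depth = hp$max_depth,
                                   subsample = hp$subsample,
                                   tree_method = "hist"),
    XGBoost = fit_xgb(X, y, cw, seed, nrounds = hp$nrounds, eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$colsample,
                      lambda = hp$reg_lambda, tree_method = "hist"),
    LightGBM = fit_xgb(X, y, cw, seed, nrounds = hp$nrounds, eta = hp$eta,
                       max_depth = 0, max_leaves = hp$max_leaves,
                       grow_policy = "lossguide", subsample = hp$subsample,
                       colsample_bytree = hp$colsample,
                       tree_method = "hist"),
    CatBoost = fit_xgb(X, y, cw, seed, nrounds = hp$nrounds, eta = hp$eta,
                       max_depth = hp$max_depth, subsample = hp$subsample,
                       lambda = hp$reg_lambda, grow_policy = "depthwise",
                       tree_method = "hist"),
    RandomForest = randomForest::randomForest(
      X, yf, ntree = hp$num_trees,
      mtry = rf_mtry(hp$mtry_frac, ncol(X)),
      nodesize = hp$min_node, classwt = c("0" = 1, "1" = cw)),
    ExtraTrees = ranger::ranger(
      x = X, y = yf, num.trees = hp$num_trees,
      mtry = rf_mtry(hp$mtry_frac, ncol(X)),
      min.node.size = hp$min_node, splitrule = "extratrees",
      probability = TRUE, importance = "impurity", seed = seed,
      num.threads = 1, class.weights = c(1, cw)),
    MLPC = nnet::nnet(X, y, size = hp$size, decay = hp$decay,
                      maxit = hp$maxit, entropy = TRUE, weights = w,
                      trace = FALSE, MaxNWts = 50000)
  ))
  structure(list(name = name, fit = fit, hyperparameters = hp,
                 class_weight = cw, seed = seed,
                 feature_names = colnames(X)),
            class = "ml_model")
}

rf_mtry <- function(frac, p) {
  if (is.null(frac)) max(1, floor(sqrt(p))) else max(1, round(frac * p))
}

fit_xgb <- function(X, y, cw, seed, nrounds, ...) {
  params <- list(objective = "binary:logistic", nthread = 1, seed = seed,
                 scale_pos_weight = cw, ...)
  booster <- xgboost::xgb.train(
    params = params, data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = as.integer(nrounds), verbose = 0)
  list(booster = booster, nrounds = nrounds)
}

# Discrete AdaBoost (SAMME) over rpart stumps/shallow trees. The staged
# score F(x) = sum_m alpha_m h_m(x) in {-1,+1} margins is mapped to a
# probability with the usual logistic link p = 1 / (1 + exp(-2F)).
fit_adaboost <- function(X, y, hp, w0) {
  n <- nrow(X)
  d <- w0 / sum(w0)
  ys <- 2 * y - 1
  df <- as.data.frame(X)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = hp$max_depth, cp = 0,
                               minsplit = 2, xval = 0)
  for (m in seq_len(hp$n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = factor(y)),
                        weights = d * n, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(d[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- hp$learning_rate * 0.5 * log((1 - err) / err)
    d <- d * exp(-alpha * ys * (2 * pred - 1))
    d <- d / sum(d)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

#' Positive-class probability predictions
#'
#' @param model A fitted `ml_model`.
#' @param X Numeric matrix; columns are reordered to the training feature
#'   order when names are present.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "ml_model"))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    missing <- setdiff(model$feature_names, colnames(X))
    if (length(missing) > 0) {
      stop(sprintf("missing feature(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  p <- switch(
    model$name,
    Ridge = ,
    Lasso = ,
    ElasticNet = as.numeric(predict(model$fit, X, type = "response")),
    SVC = ,
    NuSVC = {
      pr <- attr(predict(model$fit, X, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    },
    AdaBoost = {
      df <- as.data.frame(X)
      F <- rep(0, nrow(X))
      for (m in seq_along(model$fit$stumps)) {
        pred <- as.integer(as.character(
          predict(model$fit$stumps[[m]], df, type = "class")))
        F <- F + model$fit$alphas[m] * (2 * pred - 1)
      }
      1 / (1 + exp(-2 * F))
    },
    GradientBoosting = ,
    HistGradientBoosting = ,
    XGBoost = ,
    LightGBM = ,
    CatBoost = as.numeric(predict(model$fit$booster,
                                  xgboost::xgb.DMatrix(X))),
    RandomForest = as.numeric(predict(model$fit, X,
                                      type = "prob")[, "1"]),
    ExtraTrees = as.numeric(predict(model$fit, data = X,
                                    num.threads = 1)$predictions[, "1"]),
    MLPC = as.numeric(predict(model$fit, X))
  )
  pmin(1, pmax(0, p))
}

#' Label predictions at a probability threshold
#' @param model A fitted `ml_model`.
#' @param X Numeric matrix.
#' @param threshold Decision threshold on the positive-class probability.
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, X, threshold = 0.5) {
  as.integer(predict_prob(model, X) >= threshold)
}

# --- hyperparameter search spaces ------------------------------------------

#' Search-space parameter constructors
#'
#' `param_num` defines a continuous dimension (optionally log-scaled),
#' `param_int` an integer dimension, `param_cat` a categorical one.
#'
#' @param name Hyperparameter name.
#' @param lower,upper Bounds.
#' @param log Sample on the log scale.
#' @param choices Categorical values.
#' @return A parameter definition list.
#' @export
param_num <- function(name, lower, upper, log = FALSE) {
  list(name = name, type = "num", lower = lower, upper = upper, log = log)
}

#' @rdname param_num
#' @export
param_int <- function(name, lower, upper) {
  list(name = name, type = "int", lower = as.integer(lower),
       upper = as.integer(upper))
}

#' @rdname param_num
#' @export
param_cat <- function(name, choices) {
  list(name = name, type = "cat", choices = choices)
}

#' Shipped hyperparameter search space for an algorithm
#'
#' The spaces are this package's own, deliberately compact defaults around
#' each algorithm's key capacity and regularization knobs; they can be
#' overridden per call in [search_hyperparameters()].
#'
#' @param name One of the 15 registered algorithm names.
#' @return A list of parameter definitions (see [param_num()]).
#' @export
default_search_space <- function(name) {
  if (!name %in% names(ALGORITHMS)) {
    stop(sprintf("unknown algorithm '%s'", name), call. = FALSE)
  }
  boost_common <- list(param_int("nrounds", 30, 300),
                       param_num("eta", 0.01, 0.3, log = TRUE),
                       param_num("subsample", 0.5, 1))
  switch(name,
    Ridge = list(param_num("lambda", 1e-4, 3, log = TRUE)),
    Lasso = list(param_num("lambda", 1e-4, 3, log = TRUE)),
    ElasticNet = list(param_num("lambda", 1e-4, 3, log = TRUE),
                      param_num("alpha", 0.05, 0.95)),
    SVC = list(param_num("cost", 0.01, 100, log = TRUE),
               param_num("gamma", 1e-4, 1, log = TRUE)),
    NuSVC = list(param_num("nu", 0.05, 0.5),
                 param_num("gamma", 1e-4, 1, log = TRUE)),
    AdaBoost = list(param_int("n_estimators", 20, 150),
                    param_num("learning_rate", 0.05, 1, log = TRUE),
                    param_int("max_depth", 1, 3)),
    GradientBoosting = c(boost_common, list(param_int("max_depth", 2, 8))),
    HistGradientBoosting = c(boost_common,
                             list(param_int("max_depth", 2, 8))),
    XGBoost = c(boost_common,
                list(param_int("max_depth", 2, 8),
                     param_num("colsample", 0.5, 1),
                     param_num("reg_lambda", 0.1, 10, log = TRUE))),
    LightGBM = c(boost_common, list(param_int("max_leaves", 7, 63),
                                    param_num("colsample", 0.5, 1))),
    CatBoost = c(boost_common,
                 list(param_int("max_depth", 3, 8),
                      param_num("reg_lambda", 0.5, 10, log = TRUE))),
    RandomForest = list(param_int("num_trees", 100, 500),
                        param_num("mtry_frac", 0.1, 0.9),
                        param_int("min_node", 1, 10)),
    ExtraTrees = list(param_int("num_trees", 100, 500),
                      param_num("mtry_frac", 0.1, 0.9),
                      param_int("min_node", 1, 10)),
    MLPC = list(param_int("size", 2, 20),
                param_num("decay", 1e-4, 1, log = TRUE),
                param_int("maxit", 100, 400)),
    TabNet = list(param_int("n_steps", 2, 8), param_int("width", 4, 32))
  )
}
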
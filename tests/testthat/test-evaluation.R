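test_that("evaluation separates signal from label-permuted null data", {
  sp <- fixture_split(seed = 90, n = 120, p = 10, effect = 4)
  m <- build_model(model_spec("Ridge", list(lambda = 0.02)),
                   seed = 1)$fit(sp$train$X, sp$train$y)
  rep_sig <- evaluate_model(m, sp, folds = 5, repeats = 2, seed = 2)
  expect_gte(rep_sig$roc_auc_cv$mean, 0.99)
  expect_equal(length(rep_sig$roc_auc_cv$per_fold), 10)

  # internal consistency: composite is recomputable from the vectors
  expect_equal(rep_sig$composite,
               composite_score(rep_sig$metric_vector_train,
                               rep_sig$metric_vector_test))

  # label permutation kills the CV signal (mean over a few seeds)
  aucs <- vapply(1:5, function(s) {
    spn <- sp
    spn$train$y <- with_seed_shuffle(sp$train$y, s)
    mn <- build_model(model_spec("Ridge", list(lambda = 0.02)),
                      seed = 1)$fit(spn$train$X, spn$train$y)
    evaluate_model(mn, spn, folds = 5, repeats = 1,
                   seed = s)$roc_auc_cv$mean
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("built-in importance covers tree/linear and refuses SVM/MLP", {
  sp <- fixture_split(seed = 91, n = 130, p = 12)
  truth <- attr(sp, "informative")
  rf <- build_model(model_spec("RandomForest"), seed = 2)$fit(sp$train$X,
                                                              sp$train$y)
  bi <- builtin_importance(rf)
  top <- names(sort(bi$scores, decreasing = TRUE))[seq_along(truth)]
  expect_gte(length(intersect(top, truth)), length(truth) - 1)

  svc <- build_model(model_spec("SVC"), seed = 2)$fit(sp$train$X,
                                                      sp$train$y)
  un <- builtin_importance(svc)
  expect_s3_class(un, "unsupported_importance")
  expect_match(un$reason, "permutation")

  # lasso with one dominant coefficient ranks that feature first
  lso <- build_model(model_spec("Lasso", list(lambda = 0.15)),
                     seed = 2)$fit(sp$train$X, sp$train$y)
  bl <- builtin_importance(lso)
  expect_true(names(which.max(bl$scores)) %in% truth)
})

test_that("permutation importance is seed-stable and null-centred", {
  sp <- fixture_split(seed = 92, n = 140, p = 10)
  truth <- attr(sp, "informative")
  m <- build_model(model_spec("XGBoost", list(nrounds = 60)),
                   seed = 3)$fit(sp$train$X, sp$train$y)
  pi1 <- permutation_importance(m, sp$test$X, sp$test$y, n_repeats = 8,
                                seed = 5)
  pi2 <- permutation_importance(m, sp$test$X, sp$test$y, n_repeats = 8,
                                seed = 5)
  expect_identical(pi1$scores, pi2$scores)
  expect_true(names(which.max(pi1$scores)) %in% truth)
  # independent noise features stay within 3 SD of zero
  noise <- setdiff(names(pi1$scores), truth)
  margin <- 3 * pi1$details$sd[noise] / sqrt(pi1$details$n_repeats) + 1e-9
  expect_gt(mean(abs(pi1$scores[noise]) <= pmax(margin, 0.05)), 0.8)
})

test_that("SHAP attributions satisfy additivity and global consistency", {
  sp <- fixture_split(seed = 93, n = 130, p = 10)
  m <- build_model(model_spec("XGBoost", list(nrounds = 50)),
                   seed = 4)$fit(sp$train$X, sp$train$y)
  loc <- shap_attribution(m, sp$train$X, sp$test$X, scope = "local")
  margin <- qlogis(pmin(pmax(predict_prob(m, sp$test$X), 1e-12),
                        1 - 1e-12))
  expect_lt(max(abs(rowSums(loc$scores) + loc$baseline - margin)), 1e-3)
  glob <- shap_attribution(m, sp$train$X, sp$test$X, scope = "global")
  expect_equal(glob$scores, colMeans(abs(loc$scores)))
  top <- names(sort(glob$scores, decreasing = TRUE))[1:3]
  expect_gte(length(intersect(top, attr(sp, "informative"))), 2)

  # kernel path (SVC) keeps the additivity identity on the prob scale
  svc <- build_model(model_spec("SVC"), seed = 4)$fit(sp$train$X[, 1:6],
                                                      sp$train$y)
  lk <- shap_attribution(svc, sp$train$X[, 1:6], sp$test$X[1:4, 1:6],
                         scope = "local", seed = 6)
  pk <- predict_prob(svc, sp$test$X[1:4, 1:6])
  expect_lt(max(abs(rowSums(lk$scores) + lk$baseline - pk)), 1e-6)
})

test_that("LIME surrogates are locally faithful and sign-consistent", {
  sp <- fixture_split(seed = 94, n = 150, p = 8, effect = 3)
  m <- build_model(model_spec("Ridge", list(lambda = 0.02)),
                   seed = 5)$fit(sp$train$X, sp$train$y)
  li <- lime_attribution(m, sp$test$X[1, ], sp$train$X, seed = 8)
  expect_gt(li$details$r_squared, 0)
  # against a linear truth the surrogate signs match the coefficients
  beta <- as.numeric(coef(m$fit))[-1]
  names(beta) <- m$feature_names
  inf <- attr(sp, "informative")
  expect_true(all(sign(li$scores[inf]) == sign(beta[inf])))
  li2 <- lime_attribution(m, sp$test$X[1, ], sp$train$X, seed = 8)
  expect_identical(li$scores, li2$scores)
})
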
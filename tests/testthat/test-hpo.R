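test_that("objective values cross-check against the scoring module", {
  sp <- fixture_split(seed = 80, n = 140, p = 10)
  spec <- model_spec("Ridge", list(lambda = 0.05))
  for (obj in c("hamming", "kappa_mcc_error", "custom_score")) {
    rec <- objective_value(spec, sp, obj, seed = 4)
    expect_equal(rec$status, "ok")
    model <- build_model(spec, seed = rec$seed)$fit(sp$train$X,
                                                    sp$train$y)
    pred_va <- predict_label(model, sp$validation$X)
    expected <- switch(obj,
      hamming = mean(pred_va != sp$validation$y),
      kappa_mcc_error = kappa_mcc_error(sp$validation$y, pred_va),
      custom_score = custom_score(rec$kme_train, rec$kme_validation))
    expect_equal(rec$objective_value, expected, label = obj)
  }
  # hamming equals (fp+fn)/n from the confusion counts
  rec <- objective_value(spec, sp, "hamming", seed = 4)
  model <- build_model(spec, seed = rec$seed)$fit(sp$train$X, sp$train$y)
  cc <- confusion_counts(sp$validation$y,
                         predict_label(model, sp$validation$X))
  expect_equal(rec$objective_value,
               (cc$fp + cc$fn) / nrow(sp$validation$X))
})

test_that("failed fits become +Inf trials instead of crashing the study", {
  sp <- fixture_split(seed = 81, n = 80, p = 6)
  rec <- objective_value(model_spec("Ridge", list(lambda = -1)), sp,
                         "hamming", seed = 1)
  expect_equal(rec$status, "failed")
  expect_equal(rec$objective_value, Inf)
})

test_that("all three engines find a planted optimum", {
  sp <- fixture_split(seed = 82, n = 160, p = 8, effect = 4)
  # L1 penalty large enough to zero every coefficient vs. a working value
  space <- list(param_cat("lambda", c(10, 0.01)))
  for (eng in c("grid", "bayes", "tpe")) {
    out <- search_hyperparameters(eng, model_spec("Lasso"), sp,
                                  "kappa_mcc_error", budget = 8,
                                  seed = 7, space = space)
    expect_equal(out$best_hyperparameters$lambda, 0.01, label = eng)
    expect_lt(out$best$objective_value, 0.3)
    # returned best attains the minimum among completed trials
    vals <- vapply(out$trials, `[[`, 0, "objective_value")
    expect_equal(out$best$objective_value, min(vals), label = eng)
  }
})

test_that("grid search enumerates a small space exactly once", {
  sp <- fixture_split(seed = 83, n = 80, p = 6)
  space <- list(param_cat("lambda", c(0.01, 0.1, 1)),
                param_cat("alpha", c(0.2, 0.8)))
  out <- search_hyperparameters("grid", model_spec("ElasticNet"), sp,
                                "hamming", budget = 10, seed = 1,
                                space = space)
  expect_length(out$trials, 6)
  combos <- unique(vapply(out$trials, function(t)
    paste(t$hyperparameters$lambda, t$hyperparameters$alpha), ""))
  expect_length(combos, 6)
})

test_that("stochastic engines replay identically under a fixed seed", {
  sp <- fixture_split(seed = 84, n = 90, p = 6)
  space <- list(param_num("lambda", 1e-3, 1, log = TRUE))
  for (eng in c("bayes", "tpe")) {
    a <- search_hyperparameters(eng, model_spec("Ridge"), sp, "hamming",
                                budget = 6, seed = 21, space = space)
    b <- search_hyperparameters(eng, model_spec("Ridge"), sp, "hamming",
                                budget = 6, seed = 21, space = space)
    expect_identical(lapply(a$trials, `[[`, "hyperparameters"),
                     lapply(b$trials, `[[`, "hyperparameters"),
                     label = eng)
  }
  expect_error(search_hyperparameters("grid", model_spec("Ridge"), sp,
                                      "hamming", budget = 0), "budget")
})
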
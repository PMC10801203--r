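# End-to-end orchestration: load -> clean -> stratified test split ->
# feature-selection chain (training data only) -> resampling (train only)
# -> normalization (fit on train) -> hyperparameter search -> final fit ->
# evaluation -> prediction bundle. Every enum is validated before any data
# is touched, and the test partition is never read by any stage before the
# final evaluation.

#' Validated run configuration
#'
#' @param data A labelled `ds_dataset` (alternative to `data_path`).
#' @param data_path CSV path, loaded with [load_csv_dataset()].
#' @param label_column,positive_label Label conventions for CSV loading.
#' @param chain List of at most four [selection_step()]s (may be empty).
#' @param normalization One of `"minmax"`, `"standard"`, `"none"`.
#' @param sampling One of `"none"`, `"undersample"`, `"oversample"`,
#'   `"smote"`.
#' @param algorithm One of the 15 registry names, or `"None"` to run
#'   feature selection only.
#' @param engine,objective,trials Hyperparameter search settings (see
#'   [search_hyperparameters()]).
#' @param folds,repeats Evaluation CV design.
#' @param test_fraction,validation_fraction Partition proportions of the
#'   full dataset.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param output_dir Optional directory for run artifacts (bundle,
#'   report JSON, selected-feature list).
#' @return A validated `run_config` object.
#' @export
run_config <- function(data = NULL, data_path = NULL,
                       label_column = "label", positive_label,
                       chain = list(), normalization = "minmax",
                       sampling = "none", algorithm = "XGBoost",
                       engine = "tpe", objective = "custom_score",
                       trials = 50, folds = 5, repeats = 5,
                       test_fraction = 0.2, validation_fraction = 0.2,
                       seed = 1, output_dir = NULL) {
  normalization <- match.arg(normalization,
                             c("minmax", "standard", "none"))
  sampling <- match.arg(sampling, c("none", "undersample", "oversample",
                                    "smote"))
  engine <- match.arg(engine, c("grid", "bayes", "tpe"))
  objective <- match.arg(objective, HPO_OBJECTIVES)
  if (!(algorithm %in% c(names(ALGORITHMS), "None"))) {
    stop(sprintf("unknown algorithm '%s'; valid: None, %s", algorithm,
                 paste(names(ALGORITHMS), collapse = ", ")),
         call. = FALSE)
  }
  if (length(chain) > 4) stop("at most 4 selection steps", call. = FALSE)
  for (st in chain) {
    if (!inherits(st, "selection_step")) {
      stop("chain entries must be selection_step objects", call. = FALSE)
    }
  }
  stopifnot(trials >= 1, folds >= 2, repeats >= 1,
            test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  if (is.null(data) && is.null(data_path)) {
    stop("provide either `data` or `data_path`", call. = FALSE)
  }
  structure(list(data = data, data_path = data_path,
                 label_column = label_column,
                 positive_label = positive_label, chain = chain,
                 normalization = normalization, sampling = sampling,
                 algorithm = algorithm, engine = engine,
                 objective = objective, trials = trials, folds = folds,
                 repeats = repeats, test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

restrict_dataset <- function(ds, features) {
  new_dataset(ds$X[, features, drop = FALSE], ds$y,
              positive_label = ds$positive_label,
              sample_ids = ds$sample_ids)
}

#' Run the full training pipeline
#'
#' Executes the fixed stage order and returns the trained bundle, the
#' evaluation report, the selection result, and a manifest recording every
#' stage's inputs, outputs, and seeds. With `algorithm = "None"` only the
#' feature-selection chain runs and the selection result is returned.
#'
#' @param config A [run_config()].
#' @return A list with `bundle`, `report`, `selection`, `best_trial`,
#'   `manifest` (selection only when `algorithm = "None"`).
#' @export
run_training <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ds <- config$data %||% load_csv_dataset(config$data_path,
                                          config$label_column,
                                          config$positive_label)
  ds <- clean_dataset(ds)
  note("load", n_samples = nrow(ds$X), n_features = ncol(ds$X),
       n_cleaned = attr(ds, "n_cleaned") %||% 0L)

  split <- stratified_split(ds, config$test_fraction,
                            seed = child_seed(seed, 1L),
                            validation_fraction =
                              config$validation_fraction)
  note("split", train = nrow(split$train$X), test = nrow(split$test$X),
       validation = nrow(split$validation$X),
       seed = child_seed(seed, 1L))

  # Selection runs on the training partition only: supervised steps must
  # never see test (or validation) labels.
  selection <- if (length(config$chain) > 0) {
    run_chain(config$chain, split$train)
  } else {
    structure(list(selected = ds$feature_names,
                   per_step = data.frame(method = character(0),
                                         n_in = integer(0),
                                         n_out = integer(0))),
              class = "selection_result")
  }
  feats <- selection$selected
  note("selection", n_selected = length(feats))

  if (identical(config$algorithm, "None")) {
    manifest$stages$selection$selected <- feats
    return(list(selection = selection, manifest = manifest))
  }

  tr <- restrict_dataset(split$train, feats)
  va <- restrict_dataset(split$validation, feats)
  te <- restrict_dataset(split$test, feats)

  # hyperparameter-search phase: sample + normalize the train partition
  rs <- resample(tr$X, tr$y, method = config$sampling,
                 seed = child_seed(seed, 2L))
  norm_hpo <- fit_normalizer(rs$X, config$normalization)
  hpo_split <- structure(list(
    train = new_dataset(apply_normalizer(norm_hpo, rs$X), rs$y,
                        positive_label = ds$positive_label),
    validation = new_dataset(apply_normalizer(norm_hpo, va$X), va$y,
                             positive_label = ds$positive_label),
    seed = seed, test_fraction = config$test_fraction),
    class = "ds_split")
  hpo <- search_hyperparameters(config$engine,
                                model_spec(config$algorithm), hpo_split,
                                config$objective, budget = config$trials,
                                seed = child_seed(seed, 3L),
                                class_weight = rs$class_weight)
  note("hpo", engine = config$engine, objective = config$objective,
       trials = length(hpo$trials),
       best_objective = hpo$best$objective_value)

  # final phase: refit on train+validation with the best hyperparameters
  union_X <- rbind(tr$X, va$X)
  union_y <- c(tr$y, va$y)
  rs_final <- resample(union_X, union_y, method = config$sampling,
                       seed = child_seed(seed, 4L))
  normalizer <- fit_normalizer(rs_final$X, config$normalization)
  final_spec <- model_spec(config$algorithm, hpo$best_hyperparameters)
  model <- build_model(final_spec, class_weight = rs_final$class_weight,
                       seed = child_seed(seed, 5L)
  )$fit(apply_normalizer(normalizer, rs_final$X), rs_final$y)
  note("fit", algorithm = config$algorithm,
       class_weight = rs_final$class_weight,
       n_train = nrow(rs_final$X))

  eval_split <- structure(list(
    train = new_dataset(apply_normalizer(normalizer, union_X), union_y,
                        positive_label = ds$positive_label),
    test = new_dataset(apply_normalizer(normalizer, te$X), te$y,
                       positive_label = ds$positive_label),
    seed = seed, test_fraction = config$test_fraction),
    class = "ds_split")
  report <- evaluate_model(model, eval_split, folds = config$folds,
                           repeats = config$repeats,
                           seed = child_seed(seed, 6L))
  note("evaluate", neglog2rmsl = report$composite$neglog2rmsl,
       cv_roc_auc = report$roc_auc_cv$mean)

  bundle <- make_bundle(
    model, normalizer, ds$positive_label,
    background = apply_normalizer(normalizer, union_X),
    metadata = list(chain = vapply(config$chain, `[[`, "", "method"),
                    sampling = config$sampling,
                    normalization = config$normalization,
                    engine = config$engine, objective = config$objective,
                    master_seed = seed))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    save_bundle(bundle, file.path(config$output_dir, "model_bundle.rds"))
    writeLines(feats, file.path(config$output_dir,
                                "selected_features.txt"))
    jsonlite::write_json(
      list(metrics_test = as.list(report$metric_vector_test),
           metrics_train = as.list(report$metric_vector_train),
           composite = report$composite,
           roc_auc_cv = report$roc_auc_cv[c("mean", "sd")],
           best_hyperparameters = hpo$best_hyperparameters,
           manifest = manifest),
      file.path(config$output_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  list(bundle = bundle, report = report, selection = selection,
       best_trial = hpo$best, manifest = manifest)
}

#' Run the standalone prediction pipeline
#'
#' @param bundle_path Path to a saved bundle.
#' @param data_path CSV of new samples (no label column required).
#' @param out_path Output CSV (`sample_id,label,probability`).
#' @param explain Also write per-sample SHAP/LIME attribution JSON next to
#'   the CSV.
#' @param seed Integer seed for the explanation methods.
#' @return The prediction data frame, invisibly.
#' @export
run_prediction <- function(bundle_path, data_path, out_path,
                           explain = FALSE, seed = 1) {
  bundle <- load_bundle(bundle_path)
  newd <- load_csv_dataset(data_path, label_column = NULL,
                           positive_label = bundle$positive_label)
  newd <- clean_dataset(newd)
  preds <- predict_samples(bundle, newd)
  write.csv(preds, out_path, row.names = FALSE)
  if (explain) {
    attr_out <- explain_samples(bundle, newd, seed = seed)
    json_path <- sub("\\.csv$", "", out_path)
    jsonlite::write_json(
      list(shap = as.data.frame(attr_out$shap$scores),
           lime = lapply(attr_out$lime, function(a)
             as.list(a$scores))),
      paste0(json_path, "_attributions.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(preds)
}
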
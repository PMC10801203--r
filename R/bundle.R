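# Portable prediction bundles: a trained model, its ordered feature list,
# the fitted normalizer, the positive-class name, a compact background
# summary for SHAP, and training metadata — everything needed to score and
# explain new samples without the training platform.

BUNDLE_FORMAT_VERSION <- 1L

#' Assemble a prediction bundle
#'
#' @param model A fitted `ml_model`.
#' @param normalizer A `normalizer_state` fitted on the training data.
#' @param positive_label Class name emitted for probability >= threshold.
#' @param background Matrix of (normalized) training rows kept as the SHAP
#'   background summary; subsampled to at most 100 rows.
#' @param metadata Named list of provenance (seeds, chain, config...).
#' @param threshold Decision threshold (default 0.5).
#' @return A `model_bundle` object.
#' @export
make_bundle <- function(model, normalizer, positive_label, background,
                        metadata = list(), threshold = 0.5) {
  stopifnot(inherits(model, "ml_model"),
            inherits(normalizer, "normalizer_state"))
  feats <- model$feature_names
  if (length(feats) == 0 || anyDuplicated(feats)) {
    stop("bundle feature list must be non-empty and duplicate-free",
         call. = FALSE)
  }
  if (nrow(background) > 100) {
    background <- background[seq(1, nrow(background),
                                 length.out = 100), , drop = FALSE]
  }
  metadata <- utils::modifyList(
    list(algorithm = model$name, hyperparameters = model$hyperparameters,
         seed = model$seed, created = format(Sys.time(), tz = "UTC"),
         package_version = as.character(packageVersion("drugsense"))),
    metadata)
  structure(list(format_version = BUNDLE_FORMAT_VERSION, model = model,
                 features = feats, normalizer = normalizer,
                 positive_label = positive_label,
                 background = background[, feats, drop = FALSE],
                 threshold = threshold, metadata = metadata),
            class = "model_bundle")
}

# xgboost boosters hold external pointers; serialize them to raw bytes so
# bundles survive process restarts.
freeze_model_payload <- function(bundle) {
  if (bundle$model$name %in% c("GradientBoosting", "HistGradientBoosting",
                               "XGBoost", "LightGBM", "CatBoost")) {
    bundle$model$fit$booster_raw <-
      xgboost::xgb.save.raw(bundle$model$fit$booster)
    bundle$model$fit$booster <- NULL
  }
  bundle
}

thaw_model_payload <- function(bundle) {
  if (!is.null(bundle$model$fit$booster_raw)) {
    bundle$model$fit$booster <-
      xgboost::xgb.load.raw(bundle$model$fit$booster_raw)
    bundle$model$fit$booster_raw <- NULL
  }
  bundle
}

#' Save / load a prediction bundle
#'
#' One archive file per bundle; the format version is checked on load and
#' a mismatch is an explicit error rather than a silent misread.
#'
#' @param bundle A `model_bundle`.
#' @param path File path (conventionally `.rds`).
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns
#'   the restored `model_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(freeze_model_payload(bundle), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("bundle not found: %s", path), call. = FALSE)
  }
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle")) {
    stop("file is not a drugsense model bundle", call. = FALSE)
  }
  if (!identical(bundle$format_version, BUNDLE_FORMAT_VERSION)) {
    stop(sprintf(
      "bundle format version %s is incompatible with this package (expects %s)",
      bundle$format_version, BUNDLE_FORMAT_VERSION), call. = FALSE)
  }
  thaw_model_payload(bundle)
}

# Validate + align new data to the bundle's feature order, then normalize.
prepare_new_data <- function(bundle, new_data) {
  X <- if (inherits(new_data, "ds_dataset")) new_data$X
       else as.matrix(new_data)
  if (is.null(colnames(X))) {
    stop("new data must carry feature names", call. = FALSE)
  }
  missing <- setdiff(bundle$features, colnames(X))
  if (length(missing) > 0) {
    stop(sprintf("new data is missing required feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(colnames(X), bundle$features)
  if (length(extra) > 0) {
    warning(sprintf("ignoring %d extra column(s) not in the bundle",
                    length(extra)), call. = FALSE)
  }
  X <- X[, bundle$features, drop = FALSE]
  apply_normalizer(bundle$normalizer, X)
}

#' Predict new samples with a bundle
#'
#' Columns are reordered to the bundle's feature order, the stored
#' normalizer is applied, and labels are assigned by thresholding the
#' positive-class probability. Missing features are an error (never
#' zero-filled); extra columns are ignored with a warning.
#'
#' @param bundle A `model_bundle`.
#' @param new_data Unlabelled `ds_dataset`, matrix, or data frame with
#'   named feature columns.
#' @param threshold Optional override of the bundle's decision threshold.
#' @return Data frame with `sample_id`, `label`, `probability`.
#' @export
predict_samples <- function(bundle, new_data, threshold = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- prepare_new_data(bundle, new_data)
  thr <- threshold %||% bundle$threshold
  prob <- predict_prob(bundle$model, X)
  ids <- rownames(X) %||% sprintf("sample_%d", seq_len(nrow(X)))
  data.frame(
    sample_id = ids,
    label = ifelse(prob >= thr, bundle$positive_label,
                   paste0("not_", bundle$positive_label)),
    probability = prob,
    row.names = NULL)
}

#' Explain new samples with a bundle
#'
#' Delegates to the interpretation module using the bundle's model and its
#' stored background summary, so no training data is needed.
#'
#' @param bundle A `model_bundle`.
#' @param new_data Samples to explain (same contract as
#'   [predict_samples()]).
#' @param methods Subset of `c("shap", "lime")`; empty set is a no-op with
#'   a warning.
#' @param seed Integer seed.
#' @return Named list of `attribution_set` objects (LIME returns one per
#'   sample).
#' @export
explain_samples <- function(bundle, new_data, methods = c("shap", "lime"),
                            seed = 1) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (length(methods) == 0) {
    warning("no explanation methods requested; nothing to do",
            call. = FALSE)
    return(invisible(list()))
  }
  methods <- match.arg(methods, c("shap", "lime"), several.ok = TRUE)
  X <- prepare_new_data(bundle, new_data)
  out <- list()
  if ("shap" %in% methods) {
    out$shap <- shap_attribution(bundle$model, bundle$background, X,
                                 scope = "local", seed = seed)
  }
  if ("lime" %in% methods) {
    out$lime <- lapply(seq_len(nrow(X)), function(i) {
      lime_attribution(bundle$model, X[i, ], bundle$background,
                       seed = child_seed(seed, i))
    })
    names(out$lime) <- rownames(X)
  }
  out
}
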
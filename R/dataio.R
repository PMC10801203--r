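# Dataset container and CSV I/O under the platform's operational
# conventions: CSV only, binary labels encoded 0/1, NaN -> 0 cleaning,
# stratified test partition drawn before any preprocessing.

#' Construct a dataset object
#'
#' The in-memory container used throughout the pipeline: a numeric feature
#' matrix (rows = samples, columns = features), an optional binary label
#' vector, and the name of the class encoded as 1.
#'
#' @param X Numeric matrix, samples in rows, features in columns. Column
#'   names are required and must be unique.
#' @param y Optional integer/numeric vector of 0/1 labels aligned to rows
#'   of `X`. `NULL` for unlabelled prediction data.
#' @param positive_label Character scalar naming the class encoded as 1.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to the row names of `X` or `sample_1..n`.
#' @return An object of class `ds_dataset` with elements `X`, `y`,
#'   `sample_ids`, `feature_names`, `positive_label`.
#' @export
new_dataset <- function(X, y = NULL, positive_label = "positive",
                        sample_ids = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("feature_%d", seq_len(ncol(X)))
  }
  if (anyDuplicated(colnames(X))) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X) %||% sprintf("sample_%d", seq_len(nrow(X)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) {
    stop("sample_ids length must match nrow(X)", call. = FALSE)
  }
  rownames(X) <- sample_ids
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(X)) {
      stop("label vector length must match nrow(X)", call. = FALSE)
    }
    if (!all(y %in% c(0L, 1L))) {
      stop("labels must be encoded 0/1", call. = FALSE)
    }
  }
  structure(
    list(X = X, y = y, sample_ids = sample_ids,
         feature_names = colnames(X), positive_label = positive_label),
    class = "ds_dataset"
  )
}

#' @export
print.ds_dataset <- function(x, ...) {
  cat(sprintf("<ds_dataset> %d samples x %d features", nrow(x$X), ncol(x$X)))
  if (!is.null(x$y)) {
    cat(sprintf("; labels: %d positive ('%s') / %d negative",
                sum(x$y == 1), x$positive_label, sum(x$y == 0)))
  } else {
    cat("; unlabelled")
  }
  cat("\n")
  invisible(x)
}

#' Load a CSV dataset with a binary label column
#'
#' Reads a headered CSV, encodes the label column as 1 for
#' `positive_label` and 0 for the other class, and validates that all
#' feature columns are numeric. Categorical feature columns are rejected
#' with a message naming the offending column: only label encoding of the
#' class column is performed, never of features.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Name of the label column. Use `NULL` to load
#'   unlabelled prediction data.
#' @param positive_label Value in `label_column` to encode as 1.
#' @param id_column Optional name of a sample-id column (default: a column
#'   literally named `sample_id`, else row numbers are used).
#' @param transpose If `TRUE` the file is feature-major (rows = features)
#'   and is transposed after reading; only valid for unlabelled matrices.
#' @return A [new_dataset()] object.
#' @export
load_csv_dataset <- function(path, label_column, positive_label,
                             id_column = NULL, transpose = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id_column) && "sample_id" %in% names(df)) {
    id_column <- "sample_id"
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not present", id_column), call. = FALSE)
    }
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  y <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop(sprintf("label column '%s' not present", label_column),
           call. = FALSE)
    }
    lab <- df[[label_column]]
    df[[label_column]] <- NULL
    lab_vals <- unique(lab[!is.na(lab)])
    if (length(lab_vals) < 2) {
      stop("degenerate labels: label column has a single class",
           call. = FALSE)
    }
    if (length(lab_vals) > 2) {
      stop(sprintf(
        "label column '%s' has %d classes; this is a binary platform",
        label_column, length(lab_vals)), call. = FALSE)
    }
    if (!positive_label %in% lab_vals) {
      stop(sprintf("positive_label '%s' not found in label column",
                   positive_label), call. = FALSE)
    }
    y <- as.integer(lab == positive_label)
  }
  if (transpose) {
    if (!is.null(y)) {
      stop("transpose is only supported for unlabelled feature-major input",
           call. = FALSE)
    }
    m <- t(as.matrix(df))
    colnames(m) <- ids %||% sprintf("feature_%d", seq_len(ncol(m)))
    return(new_dataset(m, positive_label = positive_label))
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop(sprintf(
      "non-numeric feature column(s): %s. Encode categorical features before loading (label encoding is only applied to the class column).",
      paste(non_num, collapse = ", ")), call. = FALSE)
  }
  new_dataset(as.matrix(df), y = y, positive_label = positive_label,
              sample_ids = ids)
}

#' Write a dataset to CSV
#'
#' Emits the same dialect [load_csv_dataset()] reads, so datasets
#' round-trip exactly: a `sample_id` column, one column per feature, and
#' (when labels are present) a label column holding the class names.
#'
#' @param ds A `ds_dataset`.
#' @param path Output file path.
#' @param label_column Name for the label column (default `"label"`).
#' @param negative_label Class name written for samples encoded 0.
#' @export
write_dataset_csv <- function(ds, path, label_column = "label",
                              negative_label = "negative") {
  df <- data.frame(sample_id = ds$sample_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(ds$X, check.names = FALSE))
  if (!is.null(ds$y)) {
    df[[label_column]] <- ifelse(ds$y == 1, ds$positive_label,
                                 negative_label)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Replace missing feature values with zero
#'
#' The platform substitutes NaN/NA cells with 0 and performs no
#' imputation. The number of replaced cells is reported.
#'
#' @param ds A `ds_dataset`.
#' @return The cleaned dataset.
#' @export
clean_dataset <- function(ds) {
  stopifnot(inherits(ds, "ds_dataset"))
  miss <- !is.finite(ds$X)
  n_miss <- sum(miss)
  if (n_miss > 0) {
    ds$X[miss] <- 0
    ds_log(sprintf("clean_dataset: replaced %d missing cell(s) with 0",
                   n_miss))
    if (n_miss == length(ds$X)) {
      warning("all feature values were missing; matrix is now all zero",
              call. = FALSE)
    }
  }
  attr(ds, "n_cleaned") <- n_miss
  ds
}

#' Stratified train/test split
#'
#' Draws the test partition before any sampling, normalization, or
#' supervised selection can run, so test samples are never altered by
#' preprocessing. Stratified by class; deterministic for a fixed seed.
#'
#' @param ds A labelled `ds_dataset`.
#' @param test_fraction Proportion of samples assigned to the test
#'   partition, strictly between 0 and 1.
#' @param seed Integer seed controlling the draw.
#' @param validation_fraction Optional proportion (of the full dataset)
#'   carved out of the remaining training samples as a validation
#'   partition for hyperparameter search.
#' @return An object of class `ds_split` with elements `train`, `test`,
#'   optionally `validation`, plus `seed` and `test_fraction`.
#' @export
stratified_split <- function(ds, test_fraction, seed,
                             validation_fraction = NULL) {
  stopifnot(inherits(ds, "ds_dataset"))
  if (is.null(ds$y)) stop("dataset has no labels to stratify on",
                          call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  tab <- table(ds$y)
  if (any(tab < 2)) {
    stop("each class needs at least 2 samples to stratify", call. = FALSE)
  }
  n <- nrow(ds$X)
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(ds$y == cls)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  rest <- setdiff(seq_len(n), test_idx)
  val_idx <- integer(0)
  if (!is.null(validation_fraction) && validation_fraction > 0) {
    with_seed(child_seed(seed, 101L), {
      for (cls in c(0L, 1L)) {
        idx <- intersect(which(ds$y == cls), rest)
        n_val <- round(n * validation_fraction * length(idx) / length(rest))
        n_val <- max(1L, min(length(idx) - 1L, n_val))
        val_idx <- c(val_idx, sample(idx, n_val))
      }
    })
    val_idx <- sort(val_idx)
  }
  train_idx <- setdiff(rest, val_idx)
  subset_ds <- function(idx) {
    new_dataset(ds$X[idx, , drop = FALSE], ds$y[idx],
                positive_label = ds$positive_label,
                sample_ids = ds$sample_ids[idx])
  }
  out <- list(train = subset_ds(train_idx), test = subset_ds(test_idx),
              seed = as.integer(seed), test_fraction = test_fraction)
  if (length(val_idx) > 0) out$validation <- subset_ds(val_idx)
  structure(out, class = "ds_split")
}

#' @export
print.ds_split <- function(x, ...) {
  cat(sprintf("<ds_split> train %d / test %d%s (seed %d)\n",
              nrow(x$train$X), nrow(x$test$X),
              if (!is.null(x$validation))
                sprintf(" / validation %d", nrow(x$validation$X)) else "",
              x$seed))
  invisible(x)
}
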
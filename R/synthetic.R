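# Synthetic tabular fixtures with known ground truth. The generator
# emulates the shape of log-normalized expression matrices used for
# drug-sensitivity classification: optionally p >> n, a small set of truly
# informative features carrying a class-conditional Gaussian mean shift,
# block-correlated nuisance features, and tunable class imbalance.

#' Specify a synthetic classification dataset
#'
#' @param n_samples Number of samples.
#' @param n_features Number of features.
#' @param n_informative Number of truly informative features (mean-shifted
#'   between classes); the rest are pure noise.
#' @param class_balance Proportion of positive samples, in (0, 1). Class
#'   counts are exact: `round(class_balance * n_samples)` positives.
#' @param effect_size Between-class separation of informative features, in
#'   units of `noise_sd`.
#' @param noise_sd Standard deviation of the Gaussian feature noise.
#' @param correlation_block Optional `list(size =, r =)` describing blocks
#'   of equicorrelated noise features appended among the noise columns.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_samples = 200, n_features = 500,
                       n_informative = 5, class_balance = 0.5,
                       effect_size = 2, noise_sd = 1,
                       correlation_block = NULL, seed = 1) {
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features", call. = FALSE)
  }
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(correlation_block)) {
    stopifnot(is.list(correlation_block),
              all(c("size", "r") %in% names(correlation_block)))
    if (abs(correlation_block$r) > 1) stop("|r| must be <= 1", call. = FALSE)
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative,
                 class_balance = class_balance, effect_size = effect_size,
                 noise_sd = noise_sd, correlation_block = correlation_block,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a labelled dataset with known informative features
#'
#' Labels are drawn with exact class counts, then each informative feature
#' receives a class-conditional mean shift of `effect_size * noise_sd`
#' (+shift/2 for positives, -shift/2 for negatives) on top of
#' `N(0, noise_sd)` noise; all remaining features are independent noise, so
#' labels depend only on the informative set.
#'
#' @param spec A [synth_spec()].
#' @return A list with `dataset` (a `ds_dataset`) and `informative`
#'   (character vector of the truly informative feature names).
#' @export
make_classification_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples; p <- spec$n_features
  with_seed(spec$seed, {
    n_pos <- round(spec$class_balance * n)
    if (n_pos < 1 || n_pos > n - 1) {
      stop("infeasible spec: a class would be empty", call. = FALSE)
    }
    y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    X <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    colnames(X) <- sprintf("gene_%04d", seq_len(p))
    inf_idx <- sort(sample.int(p, spec$n_informative))
    shift <- spec$effect_size * spec$noise_sd
    for (j in inf_idx) {
      X[, j] <- X[, j] + ifelse(y == 1, shift / 2, -shift / 2)
    }
    if (!is.null(spec$correlation_block)) {
      bl <- spec$correlation_block
      noise_idx <- setdiff(seq_len(p), inf_idx)
      if (length(noise_idx) >= bl$size) {
        target <- noise_idx[seq_len(bl$size)]
        Xb <- equicorrelated_block(n, bl$size, bl$r,
                                   child_seed(spec$seed, 7L)) * spec$noise_sd
        X[, target] <- Xb
      }
    }
    ds <- new_dataset(X, y, positive_label = "sensitive")
    list(dataset = ds, informative = colnames(X)[inf_idx])
  })
}

# Draw an n x k matrix with exact equicorrelation r between columns
# (Gaussian, unit variance), via the Cholesky factor of the
# equicorrelation matrix. Feasible iff r >= -1/(k-1).
equicorrelated_block <- function(n, k, r, seed) {
  if (k == 1) {
    return(with_seed(seed, matrix(rnorm(n), n, 1)))
  }
  S <- matrix(r, k, k); diag(S) <- 1
  ch <- tryCatch(chol(S), error = function(e) {
    stop("infeasible block correlation (matrix not positive definite)",
         call. = FALSE)
  })
  with_seed(seed, matrix(rnorm(n * k), n, k) %*% ch)
}

#' Generate a dataset of equicorrelated feature blocks
#'
#' Builds consecutive blocks of features with within-block correlation `r`
#' and independence across blocks — the fixture used to exercise
#' correlation pruning.
#'
#' @param n Number of samples.
#' @param block Features per block.
#' @param r Within-block correlation.
#' @param seed Integer seed.
#' @param n_blocks Number of blocks (default 1).
#' @return An unlabelled `ds_dataset` with `block * n_blocks` features
#'   named `blk<b>_f<j>`.
#' @export
make_correlated_block <- function(n, block, r, seed, n_blocks = 1) {
  mats <- lapply(seq_len(n_blocks), function(b) {
    m <- equicorrelated_block(n, block, r, child_seed(seed, b))
    colnames(m) <- sprintf("blk%d_f%d", b, seq_len(block))
    m
  })
  new_dataset(do.call(cbind, mats))
}

#' Generate a small-n / large-p overfit-prone split
#'
#' A fixture on which flexible, unregularized models memorize the training
#' partition (train error near zero) while validation error stays
#' materially higher — the regime the controlled-fitting objective is
#' designed to penalize. Defaults: 60 samples, 300 features, 3 informative
#' with a moderate effect, split 30/15/15 train/validation/test.
#'
#' @param seed Integer seed.
#' @param n_samples,n_features,n_informative,effect_size Generator
#'   parameters; see [synth_spec()].
#' @return A `ds_split` with train, validation, and test partitions.
#' @export
make_overfit_prone <- function(seed, n_samples = 60, n_features = 300,
                               n_informative = 3, effect_size = 1.5) {
  spec <- synth_spec(n_samples = n_samples, n_features = n_features,
                     n_informative = n_informative, class_balance = 0.5,
                     effect_size = effect_size, seed = seed)
  gen <- make_classification_data(spec)
  sp <- stratified_split(gen$dataset, test_fraction = 0.25,
                         seed = child_seed(seed, 11L),
                         validation_fraction = 0.25)
  attr(sp, "informative") <- gen$informative
  sp
}
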
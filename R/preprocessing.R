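# Normalization and class-imbalance resampling. Both operate strictly on
# the training partition: normalizer parameters are learned from training
# data only, and the resampling API takes no test data by construction.

#' Fit a feature normalizer on training data
#'
#' `minmax` stores per-feature (min, range); `standard` stores per-feature
#' (mean, population SD — divisor n); `none` stores nothing and transforms
#' as the identity. Zero-range / zero-SD features are mapped to 0 and
#' reported.
#'
#' @param train_X Numeric training matrix (samples x features).
#' @param method One of `"minmax"`, `"standard"`, `"none"`.
#' @return A `normalizer_state` object.
#' @export
fit_normalizer <- function(train_X, method = c("minmax", "standard",
                                               "none")) {
  method <- match.arg(method)
  state <- list(method = method, feature_names = colnames(train_X))
  if (method == "minmax") {
    state$min <- apply(train_X, 2, min)
    state$range <- apply(train_X, 2, max) - state$min
    n_flat <- sum(state$range == 0)
    if (n_flat > 0) {
      ds_log(sprintf("fit_normalizer: %d zero-range feature(s) map to 0",
                     n_flat))
    }
  } else if (method == "standard") {
    n <- nrow(train_X)
    state$mean <- colMeans(train_X)
    state$sd <- sqrt(colMeans(train_X^2) - state$mean^2)  # population SD
    n_flat <- sum(state$sd == 0)
    if (n_flat > 0) {
      ds_log(sprintf("fit_normalizer: %d zero-SD feature(s) map to 0",
                     n_flat))
    }
  }
  structure(state, class = "normalizer_state")
}

#' Apply a fitted normalizer
#'
#' Applies the training-derived parameters to any matrix with the same
#' feature set. Values outside the training range are NOT clipped, so test
#' values may fall outside `[0,1]` under min-max scaling.
#'
#' @param state A `normalizer_state` from [fit_normalizer()].
#' @param X Matrix whose columns match the fitted feature set.
#' @return The transformed matrix.
#' @export
apply_normalizer <- function(state, X) {
  stopifnot(inherits(state, "normalizer_state"))
  if (state$method == "none") return(X)
  if (!is.null(state$feature_names)) {
    if (is.null(colnames(X)) ||
        !identical(colnames(X), state$feature_names)) {
      stop("feature set does not match the fitted normalizer",
           call. = FALSE)
    }
  }
  if (state$method == "minmax") {
    rng <- ifelse(state$range == 0, 1, state$range)
    out <- sweep(sweep(X, 2, state$min), 2, rng, "/")
    out[, state$range == 0] <- 0
  } else {
    s <- ifelse(state$sd == 0, 1, state$sd)
    out <- sweep(sweep(X, 2, state$mean), 2, s, "/")
    out[, state$sd == 0] <- 0
  }
  out
}

#' Resample a training partition to balance classes
#'
#' `undersample` randomly removes majority samples to parity; `oversample`
#' randomly duplicates minority samples to parity; `smote` interpolates
#' synthetic minority samples to parity (k nearest minority neighbours,
#' uniform interpolation); `none` leaves the data untouched but attaches
#' the class-imbalance weight (majority/minority count ratio) for the fit
#' stage. The test partition never enters this function.
#'
#' @param train_X Training feature matrix.
#' @param train_y Training 0/1 labels.
#' @param method One of `"undersample"`, `"oversample"`, `"smote"`,
#'   `"none"`.
#' @param seed Integer seed.
#' @param k_neighbors SMOTE neighbourhood size (default 5).
#' @return A list with `X`, `y`, and `class_weight` (the majority/minority
#'   ratio of the *input* labels; 1 after active resampling).
#' @export
resample <- function(train_X, train_y,
                     method = c("none", "undersample", "oversample",
                                "smote"),
                     seed = 1, k_neighbors = 5) {
  method <- match.arg(method)
  train_y <- as.integer(train_y)
  tab <- table(factor(train_y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  majority <- 1L - minority
  n_min <- sum(train_y == minority); n_maj <- sum(train_y == majority)
  imbalance <- n_maj / n_min

  if (method == "none") {
    return(list(X = train_X, y = train_y, class_weight = imbalance))
  }
  with_seed(seed, {
    if (method == "undersample") {
      keep_maj <- sample(which(train_y == majority), n_min)
      idx <- sort(c(which(train_y == minority), keep_maj))
      X <- train_X[idx, , drop = FALSE]; y <- train_y[idx]
    } else if (method == "oversample") {
      extra <- sample(which(train_y == minority), n_maj - n_min,
                      replace = TRUE)
      idx <- c(seq_along(train_y), extra)
      X <- train_X[idx, , drop = FALSE]; y <- train_y[idx]
      rownames(X) <- make.unique(rownames(X))
    } else {
      min_idx <- which(train_y == minority)
      n_new <- n_maj - n_min
      if (n_min < 2) {
        ds_log("smote: minority class too small, falling back to duplication")
        extra <- rep(min_idx, length.out = n_new)
        idx <- c(seq_along(train_y), extra)
        X <- train_X[idx, , drop = FALSE]; y <- train_y[idx]
        rownames(X) <- make.unique(rownames(X))
      } else {
        k <- min(k_neighbors, n_min - 1)
        if (k < k_neighbors) {
          ds_log(sprintf("smote: reducing neighbours to %d (minority n=%d)",
                         k, n_min))
        }
        Xm <- train_X[min_idx, , drop = FALSE]
        dd <- as.matrix(dist(Xm))
        diag(dd) <- Inf
        nn <- matrix(0L, n_min, k)
        for (i in seq_len(n_min)) nn[i, ] <- order(dd[i, ])[seq_len(k)]
        base <- sample.int(n_min, n_new, replace = TRUE)
        pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
        gap <- runif(n_new)
        synth <- Xm[base, , drop = FALSE] +
          gap * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
        rownames(synth) <- sprintf("smote_%d", seq_len(n_new))
        X <- rbind(train_X, synth)
        y <- c(train_y, rep(minority, n_new))
      }
    }
    list(X = X, y = y, class_weight = 1)
  })
}
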
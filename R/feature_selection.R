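# Feature selection: unsupervised filters (variance, MAD), matrix-
# factorization and clustering reducers, forest-based supervised methods,
# model-X knockoffs with FDR control, correlation pruning, exhaustive
# small-subset search, and the four-slot chain runner with provenance.

SELECTION_METHODS <- c("HVF", "MedianMAD", "SelByPCA", "RandomProjection",
                       "SelByClustering", "SelByNMF", "SelectByRF",
                       "RecursiveFeatElim", "SeqFeatSel", "ModelX",
                       "RemoveHighCorrFeat", "IterativeFeatSel", "None")

SUPERVISED_METHODS <- c("SelectByRF", "RecursiveFeatElim", "SeqFeatSel",
                        "ModelX", "IterativeFeatSel")

#' Define one step of a feature-selection chain
#'
#' @param method One of the registered method names (see
#'   `SELECTION_METHODS`): `HVF`, `MedianMAD`, `SelByPCA`,
#'   `RandomProjection`, `SelByClustering`, `SelByNMF`, `SelectByRF`,
#'   `RecursiveFeatElim`, `SeqFeatSel`, `ModelX`, `RemoveHighCorrFeat`,
#'   `IterativeFeatSel`, or `None`.
#' @param k Target feature count, for methods that take one.
#' @param params Method-specific settings (e.g. `threshold` for
#'   `RemoveHighCorrFeat`, `fdr_target` for `ModelX`, `max_size` for
#'   `IterativeFeatSel`).
#' @param seed Integer seed for stochastic methods.
#' @return A `selection_step` list.
#' @export
selection_step <- function(method, k = NULL, params = list(), seed = 1) {
  if (!method %in% SELECTION_METHODS) {
    stop(sprintf("unknown selection method '%s'; valid: %s", method,
                 paste(SELECTION_METHODS, collapse = ", ")), call. = FALSE)
  }
  needs_k <- c("HVF", "SelByPCA", "RandomProjection", "SelByClustering",
               "SelByNMF", "SelectByRF", "RecursiveFeatElim", "SeqFeatSel")
  if (method %in% needs_k && (is.null(k) || k < 1)) {
    stop(sprintf("method %s requires k >= 1", method), call. = FALSE)
  }
  structure(list(method = method, k = k, params = params,
                 seed = as.integer(seed)),
            class = "selection_step")
}

#' Highly variable features
#'
#' Keeps the `k` features with the largest sample variance; ties broken by
#' input order.
#'
#' @param X Feature matrix with column names.
#' @param k Number of features to keep.
#' @return Character vector of selected feature names.
#' @export
hvf_select <- function(X, k) {
  if (k > ncol(X)) stop("k exceeds the number of features", call. = FALSE)
  v <- apply(X, 2, var)
  colnames(X)[order(-v, seq_along(v))[seq_len(k)]]
}

#' Median-of-MAD filter
#'
#' Keeps features whose median absolute deviation strictly exceeds the
#' median of all features' MADs (roughly the more-dispersed half). When
#' every MAD is equal the strict-exceed set is empty; all features are
#' returned with a warning.
#'
#' @param X Feature matrix with column names.
#' @return Character vector of selected feature names.
#' @export
median_mad_select <- function(X) {
  if (ncol(X) < 2) stop("need at least 2 features", call. = FALSE)
  mads <- apply(X, 2, mad)
  keep <- mads > median(mads)
  if (!any(keep)) {
    warning("all features have equal MAD; returning all features",
            call. = FALSE)
    return(colnames(X))
  }
  colnames(X)[keep]
}

#' Prune highly correlated features
#'
#' Greedy scan of the upper-triangular absolute Pearson correlations in
#' input order: whenever `|r| > threshold` for a pair, the later-ordered
#' feature is dropped. No surviving pair exceeds the threshold.
#'
#' @param X Feature matrix with column names.
#' @param threshold Correlation threshold in (0, 1]; default 0.9.
#' @return Character vector of surviving feature names.
#' @export
remove_high_corr <- function(X, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  p <- ncol(X)
  if (p < 2) return(colnames(X))
  cm <- suppressWarnings(abs(cor(X)))
  cm[is.na(cm)] <- 0  # constant columns correlate with nothing
  keep <- rep(TRUE, p)
  for (j in 2:p) {
    prior <- which(keep[seq_len(j - 1)])
    if (length(prior) > 0 && any(cm[prior, j] > threshold)) {
      keep[j] <- FALSE
    }
  }
  colnames(X)[keep]
}

# Column-standardize, guarding constant columns (they become all-zero).
scale_safe <- function(X) {
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
}

#' Unsupervised projection/factorization-based selection
#'
#' * `SelByPCA` — features ranked by their maximum absolute loading across
#'   the smallest set of principal components explaining at least
#'   `var_explained` (default 90%) of the variance.
#' * `RandomProjection` — a sparse random projection is drawn and original
#'   features are ranked by their aggregate absolute projection weight.
#' * `SelByClustering` — features are clustered into `k` groups on their
#'   standardized profiles (k-means); the feature nearest each cluster
#'   center is taken as the representative.
#' * `SelByNMF` — non-negative matrix factorization (multiplicative
#'   updates); features ranked by their maximum basis weight across
#'   components. Data containing negatives are shifted by their minimum
#'   first (log-expression can be negative).
#'
#' @param X Feature matrix with column names.
#' @param method One of `"SelByPCA"`, `"RandomProjection"`,
#'   `"SelByClustering"`, `"SelByNMF"`.
#' @param k Number of features to keep.
#' @param seed Integer seed; output is deterministic per seed.
#' @param var_explained Variance fraction defining the PCA component set.
#' @return Character vector of selected feature names.
#' @export
unsupervised_select <- function(X, method = c("SelByPCA",
                                              "RandomProjection",
                                              "SelByClustering",
                                              "SelByNMF"),
                                k, seed = 1, var_explained = 0.9) {
  method <- match.arg(method)
  if (k > ncol(X)) stop("k exceeds the number of features", call. = FALSE)
  p <- ncol(X)
  if (method == "SelByPCA") {
    pc <- prcomp(scale_safe(X), center = FALSE, scale. = FALSE)
    ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_comp <- max(1, which(ve >= var_explained)[1])
    load <- abs(pc$rotation[, seq_len(n_comp), drop = FALSE])
    score <- apply(load, 1, max)
    return(colnames(X)[order(-score, seq_len(p))[seq_len(k)]])
  }
  if (method == "RandomProjection") {
    # sparse (Achlioptas-style) projection; feature score = aggregate |weight|
    n_comp <- max(k, min(p, ceiling(4 * log(max(nrow(X), 2)))))
    density <- 1 / sqrt(p)
    R <- with_seed(seed, {
      vals <- sample(c(-1, 0, 1), p * n_comp, replace = TRUE,
                     prob = c(density / 2, 1 - density, density / 2))
      matrix(vals / sqrt(density * n_comp), p, n_comp)
    })
    score <- rowSums(abs(R))
    return(colnames(X)[order(-score, seq_len(p))[seq_len(k)]])
  }
  if (method == "SelByClustering") {
    profiles <- t(scale_safe(X))  # features x samples
    km <- with_seed(seed, kmeans(profiles, centers = k, nstart = 5,
                                 iter.max = 50))
    reps <- vapply(seq_len(k), function(cl) {
      members <- which(km$cluster == cl)
      d <- rowSums((profiles[members, , drop = FALSE] -
                      matrix(km$centers[cl, ], length(members),
                             ncol(profiles), byrow = TRUE))^2)
      members[which.min(d)]
    }, integer(1))
    return(colnames(X)[sort(reps)])
  }
  # SelByNMF
  Xn <- X
  if (min(Xn) < 0) {
    ds_log("SelByNMF: shifting data by its minimum to enforce non-negativity")
    Xn <- Xn - min(Xn)
  }
  r <- max(1, min(k, nrow(Xn) - 1, p - 1))
  fac <- nmf_factorize(Xn, rank = r, seed = seed)
  score <- apply(fac$H, 2, max)
  colnames(X)[order(-score, seq_len(p))[seq_len(k)]]
}

# Compact Lee-Seung multiplicative-update NMF: X (n x p, non-negative)
# ~ W (n x r) H (r x p), Frobenius loss. W columns normalized to unit sum
# so H carries comparable basis weights.
nmf_factorize <- function(X, rank, seed = 1, n_iter = 200, eps = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    W <- matrix(runif(n * rank, 0.1, 1), n, rank)
    H <- matrix(runif(rank * p, 0.1, 1), rank, p)
    for (it in seq_len(n_iter)) {
      H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
      W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
    }
    s <- colSums(W) + eps
    W <- sweep(W, 2, s, "/")
    H <- sweep(H, 1, s, "*")
    list(W = W, H = H)
  })
}

#' Supervised model-based selection
#'
#' * `SelectByRF` — top-`k` features by random-forest impurity importance.
#' * `RecursiveFeatElim` — refits a forest and drops the lowest-importance
#'   feature (or `step` features) until `k` remain.
#' * `SeqFeatSel` — greedy forward selection by cross-validated KME until
#'   `k` features are chosen.
#'
#' @param X Feature matrix with column names.
#' @param y 0/1 labels (both classes must be present).
#' @param method One of `"SelectByRF"`, `"RecursiveFeatElim"`,
#'   `"SeqFeatSel"`.
#' @param k Number of features to keep.
#' @param seed Integer seed; deterministic per seed.
#' @param num_trees Forest size for the forest-based methods.
#' @param step Features dropped per elimination round (default 1).
#' @return Character vector of selected feature names.
#' @export
supervised_select <- function(X, y, method = c("SelectByRF",
                                               "RecursiveFeatElim",
                                               "SeqFeatSel"),
                              k, seed = 1, num_trees = 300, step = 1) {
  method <- match.arg(method)
  if (k > ncol(X)) stop("k exceeds the number of features", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  yf <- factor(y, levels = c(0, 1))
  rf_importance <- function(Xs, sub_seed) {
    fit <- ranger::ranger(x = Xs, y = yf, num.trees = num_trees,
                          importance = "impurity", seed = sub_seed,
                          num.threads = 1)
    fit$variable.importance
  }
  if (method == "SelectByRF") {
    imp <- rf_importance(X, seed)
    return(colnames(X)[order(-imp, seq_len(ncol(X)))[seq_len(k)]])
  }
  if (method == "RecursiveFeatElim") {
    surv <- colnames(X)
    round <- 0L
    while (length(surv) > k) {
      round <- round + 1L
      imp <- rf_importance(X[, surv, drop = FALSE],
                           child_seed(seed, round))
      n_drop <- min(step, length(surv) - k)
      drop <- surv[order(imp, seq_along(imp))[seq_len(n_drop)]]
      surv <- setdiff(surv, drop)
    }
    return(surv)
  }
  # SeqFeatSel: greedy forward by cross-validated KME
  chosen <- character(0)
  remaining <- colnames(X)
  for (slot in seq_len(k)) {
    scores <- vapply(remaining, function(f) {
      cv_subset_score(X, y, c(chosen, f), seed = child_seed(seed, slot))
    }, numeric(1))
    best <- remaining[order(scores, seq_along(scores))[1]]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

# Stratified-CV KME of a k-nearest-neighbour classifier on a candidate
# feature subset; the shared scorer behind SeqFeatSel and IterativeFeatSel.
# kNN is used because it captures interactions (e.g. XOR pairs) that a
# linear scorer would miss.
cv_subset_score <- function(X, y, features, folds = 3, knn_k = 5,
                            seed = 1) {
  Xs <- scale_safe(X[, features, drop = FALSE])
  fold <- make_folds(y, folds, seed)
  errs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2) return(1)
    kk <- min(knn_k, sum(tr) - 1)
    pred <- as.integer(as.character(
      class::knn(Xs[tr, , drop = FALSE], Xs[te, , drop = FALSE],
                 factor(y[tr]), k = kk)))
    kappa_mcc_error(y[te], pred)
  }, numeric(1))
  mean(errs)
}

#' Model-X knockoff selection with FDR control
#'
#' Constructs second-moment (equicorrelated Gaussian) knockoff copies of
#' the features, computes the importance statistic
#' `W_j = |beta_j| - |beta_j~|` from an L1-penalized logistic fit on the
#' augmented matrix, and applies the knockoff+ threshold at `fdr_target`.
#' Features with `W >= threshold` are returned; on null data the expected
#' false discovery rate is controlled at `fdr_target`.
#'
#' @param X Feature matrix (n > 2 rows) with column names.
#' @param y 0/1 labels.
#' @param fdr_target Target false discovery rate in (0, 1).
#' @param seed Integer seed.
#' @return Character vector of selected feature names (possibly empty).
#' @export
modelx_knockoff_select <- function(X, y, fdr_target = 0.2, seed = 1) {
  if (fdr_target <= 0 || fdr_target >= 1) {
    stop("fdr_target must lie strictly in (0, 1)", call. = FALSE)
  }
  if (nrow(X) <= 2) stop("need more than 2 samples", call. = FALSE)
  Xk <- make_knockoffs(X, seed = seed)
  aug <- cbind(X, Xk)
  colnames(aug) <- c(colnames(X), paste0(colnames(X), "_ko"))
  cv <- with_seed(child_seed(seed, 3L),
                  glmnet::cv.glmnet(aug, factor(y), family = "binomial",
                                    alpha = 1, nfolds = 5,
                                    standardize = TRUE))
  b <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  p <- ncol(X)
  W <- abs(b[seq_len(p)]) - abs(b[p + seq_len(p)])
  thr <- knockoff_plus_threshold(W, fdr_target)
  colnames(X)[W >= thr & W > 0]
}

# Second-moment equicorrelated Gaussian knockoffs. Columns are
# standardized, the correlation matrix is shrunk toward the identity when
# near-singular (logged), and knockoffs are drawn as
#   Xk = X (I - Sigma^-1 S) + Z chol(2S - S Sigma^-1 S),
# then mapped back to the original scale.
make_knockoffs <- function(X, seed = 1) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd); s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  Sigma <- cor(Xs)
  Sigma[is.na(Sigma)] <- 0; diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    gamma <- min(0.5, (1e-4 - min(ev)) / (1 - min(ev)) + 0.05)
    ds_log(sprintf(
      "make_knockoffs: covariance near-singular, shrinking (gamma=%.3f)",
      gamma))
    Sigma <- (1 - gamma) * Sigma + gamma * diag(p)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  }
  s_eq <- rep(min(1, 2 * min(ev)), p)
  Sinv_S <- solve(Sigma, diag(s_eq, p))
  V <- 2 * diag(s_eq, p) - diag(s_eq, p) %*% Sinv_S
  # numerical symmetrization + jitter for the Cholesky factor
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e) chol(V + 1e-8 * diag(p)))
  Z <- with_seed(child_seed(seed, 1L), matrix(rnorm(n * p), n, p))
  Xk <- Xs %*% (diag(p) - Sinv_S) + Z %*% ch
  sweep(sweep(Xk, 2, s, "*"), 2, mu, "+")
}

# knockoff+ threshold: smallest t with
# (1 + #{W_j <= -t}) / max(1, #{W_j >= t}) <= q.
knockoff_plus_threshold <- function(W, q) {
  ts <- sort(unique(abs(W[W != 0])))
  for (t in ts) {
    fdp <- (1 + sum(W <= -t)) / max(1, sum(W >= t))
    if (fdp <= q) return(t)
  }
  Inf
}

#' Exhaustive search for the best 1-3 feature subset
#'
#' Scores every feature subset of size `1..max_size` by stratified
#' cross-validated KME and returns the best one. Ties are broken toward
#' the smaller subset, then by feature order. Deliberately guarded: the
#' enumeration is combinatorial, so the call errors above `cap` features
#' (run reducing steps first to get below it).
#'
#' @param X Feature matrix with column names.
#' @param y 0/1 labels.
#' @param max_size Largest subset size to consider (at most 3).
#' @param scorer Function `(X, y, features, seed)` returning a loss to
#'   minimize; defaults to the shared kNN cross-validation scorer.
#' @param seed Integer seed.
#' @param cap Maximum number of candidate features when `max_size >= 3`
#'   (default 50).
#' @return Character vector with the best subset (length <= `max_size`).
#' @export
iterative_select <- function(X, y, max_size = 3, scorer = NULL, seed = 1,
                             cap = 50) {
  stopifnot(max_size >= 1, max_size <= 3)
  p <- ncol(X)
  if (max_size >= 3 && p > cap) {
    stop(sprintf(
      "%d features is too many for exhaustive size-%d search (cap %d); run reducing selection steps first",
      p, max_size, cap), call. = FALSE)
  }
  if (is.null(scorer)) {
    scorer <- function(X, y, features, seed) {
      cv_subset_score(X, y, features, seed = seed)
    }
  }
  best <- NULL; best_score <- Inf
  for (size in seq_len(min(max_size, p))) {
    subsets <- combn(colnames(X), size, simplify = FALSE)
    for (sub in subsets) {
      sc <- scorer(X, y, sub, seed)
      if (sc < best_score) {
        best <- sub; best_score <- sc
      }
    }
  }
  best
}

#' Run a chain of up to four selection steps
#'
#' Steps are applied in order, each operating only on the features that
#' survived the previous step, so survivor counts are non-increasing.
#' `None` steps pass through. Per-step provenance (method, input/output
#' counts) is recorded. An empty intermediate survivor set aborts with a
#' diagnostic naming the step.
#'
#' @param steps List of at most four [selection_step()] objects.
#' @param ds A `ds_dataset`; labels are required when any step is
#'   supervised.
#' @return A `selection_result` with `selected` (ordered feature names)
#'   and `per_step` (a data frame of method, n_in, n_out).
#' @export
run_chain <- function(steps, ds) {
  stopifnot(inherits(ds, "ds_dataset"))
  if (length(steps) > 4) stop("at most 4 selection steps", call. = FALSE)
  lapply(steps, function(s) {
    if (!inherits(s, "selection_step")) {
      stop("steps must be selection_step objects", call. = FALSE)
    }
  })
  supervised <- vapply(steps, function(s) s$method %in% SUPERVISED_METHODS,
                       logical(1))
  if (any(supervised) && is.null(ds$y)) {
    stop("supervised selection steps require labels", call. = FALSE)
  }
  surv <- ds$feature_names
  prov <- data.frame(method = character(0), n_in = integer(0),
                     n_out = integer(0))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    Xs <- ds$X[, surv, drop = FALSE]
    n_in <- length(surv)
    out <- switch(
      st$method,
      None = surv,
      HVF = hvf_select(Xs, st$k),
      MedianMAD = median_mad_select(Xs),
      RemoveHighCorrFeat = remove_high_corr(
        Xs, threshold = st$params$threshold %||% 0.9),
      SelByPCA = ,
      RandomProjection = ,
      SelByClustering = ,
      SelByNMF = unsupervised_select(
        Xs, st$method, st$k, seed = st$seed,
        var_explained = st$params$var_explained %||% 0.9),
      SelectByRF = ,
      RecursiveFeatElim = ,
      SeqFeatSel = supervised_select(
        Xs, ds$y, st$method, st$k, seed = st$seed,
        num_trees = st$params$num_trees %||% 300,
        step = st$params$step %||% 1),
      ModelX = modelx_knockoff_select(
        Xs, ds$y, fdr_target = st$params$fdr_target %||% 0.2,
        seed = st$seed),
      IterativeFeatSel = iterative_select(
        Xs, ds$y, max_size = st$params$max_size %||% 3, seed = st$seed,
        cap = st$params$cap %||% 50)
    )
    if (length(out) == 0) {
      stop(sprintf("step %d (%s) left no surviving features", i,
                   st$method), call. = FALSE)
    }
    prov <- rbind(prov, data.frame(method = st$method, n_in = n_in,
                                   n_out = length(out)))
    surv <- out
  }
  structure(list(selected = surv, per_step = prov),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  print(x$per_step, row.names = FALSE)
  cat("selected:", paste(head(x$selected, 10), collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}
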
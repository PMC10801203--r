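# Hyperparameter search: one objective evaluator (fit on train, score on a
# held-out validation partition) and three interchangeable engines —
# exhaustive grid over a discretized space, sequential model-based
# optimization with a Gaussian-process surrogate and expected improvement
# ("bayes"), and a tree-structured Parzen estimator sampler ("tpe").
# All three minimize; failed fits score +Inf instead of aborting the study.

HPO_OBJECTIVES <- c("hamming", "kappa_mcc_error", "custom_score")

#' Evaluate one hyperparameter configuration
#'
#' Fits the model on the training partition and scores it on the
#' validation partition. `hamming` is the validation Hamming loss,
#' `kappa_mcc_error` the validation KME, and `custom_score` the
#' controlled-fitting objective
#' `KME_validation * |KME_train - KME_validation|`. Lower is better for
#' all three.
#'
#' @param spec A [model_spec()] (its hyperparameters are the trial's).
#' @param split A `ds_split` with `train` and `validation` partitions.
#' @param objective_name One of `"hamming"`, `"kappa_mcc_error"`,
#'   `"custom_score"`.
#' @param class_weight Positive-class weight forwarded to the fit.
#' @param seed Integer seed for the fit.
#' @return A `trial_record` list with `hyperparameters`, `objective_name`,
#'   `objective_value`, `kme_train`, `kme_validation`, `status`, `seed`.
#' @export
objective_value <- function(spec, split, objective_name, class_weight = 1,
                            seed = 1) {
  objective_name <- match.arg(objective_name, HPO_OBJECTIVES)
  if (is.null(split$validation)) {
    stop("split must carry a validation partition", call. = FALSE)
  }
  rec <- list(hyperparameters = spec$hyperparameters,
              objective_name = objective_name, seed = as.integer(seed),
              status = "ok", kme_train = NA_real_,
              kme_validation = NA_real_)
  res <- tryCatch({
    model <- build_model(spec, class_weight = class_weight,
                         seed = seed)$fit(split$train$X, split$train$y)
    pred_tr <- predict_label(model, split$train$X)
    pred_va <- predict_label(model, split$validation$X)
    kme_tr <- kappa_mcc_error(split$train$y, pred_tr)
    kme_va <- kappa_mcc_error(split$validation$y, pred_va)
    obj <- switch(objective_name,
                  hamming = mean(pred_va != split$validation$y),
                  kappa_mcc_error = kme_va,
                  custom_score = custom_score(kme_tr, kme_va))
    list(obj = obj, kme_tr = kme_tr, kme_va = kme_va)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    rec$status <- "failed"
    rec$message <- conditionMessage(res)
    rec$objective_value <- Inf
  } else {
    rec$objective_value <- res$obj
    rec$kme_train <- res$kme_tr
    rec$kme_validation <- res$kme_va
  }
  structure(rec, class = "trial_record")
}

# --- space sampling helpers -------------------------------------------------

# Map a value in [0,1] onto a parameter's native scale.
unit_to_param <- function(pd, u) {
  if (pd$type == "cat") {
    return(pd$choices[[pmin(length(pd$choices),
                            1 + floor(u * length(pd$choices)))]])
  }
  lo <- pd$lower; hi <- pd$upper
  v <- if (isTRUE(pd$log)) exp(log(lo) + u * (log(hi) - log(lo)))
       else lo + u * (hi - lo)
  if (pd$type == "int") as.integer(round(v)) else v
}

sample_config <- function(space) {
  cfg <- lapply(space, function(pd) unit_to_param(pd, runif(1)))
  names(cfg) <- vapply(space, `[[`, "", "name")
  cfg
}

# Encode a configuration back to [0,1]^d for the surrogate models.
config_to_unit <- function(space, cfg) {
  vapply(space, function(pd) {
    v <- cfg[[pd$name]]
    if (pd$type == "cat") {
      (match(v, pd$choices) - 0.5) / length(pd$choices)
    } else if (isTRUE(pd$log)) {
      (log(v) - log(pd$lower)) / (log(pd$upper) - log(pd$lower))
    } else {
      (v - pd$lower) / (pd$upper - pd$lower)
    }
  }, numeric(1))
}

# --- engines ----------------------------------------------------------------

grid_configs <- function(space, budget) {
  d <- length(space)
  levels_per <- vapply(space, function(pd) {
    if (pd$type == "cat") length(pd$choices) else 1L
  }, integer(1))
  num_dims <- which(vapply(space, function(pd) pd$type != "cat",
                           logical(1)))
  # grow numeric resolutions round-robin while the grid fits the budget
  repeat {
    grown <- FALSE
    for (j in num_dims) {
      trial <- levels_per
      trial[j] <- trial[j] + 1L
      if (prod(trial) <= budget) {
        levels_per <- trial
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  axes <- lapply(seq_len(d), function(j) {
    pd <- space[[j]]
    if (pd$type == "cat") return(pd$choices)
    g <- levels_per[j]
    u <- if (g == 1) 0.5 else seq(0, 1, length.out = g)
    unique(lapply(u, function(x) unit_to_param(pd, x)))
  })
  combos <- expand.grid(lapply(axes, seq_along))
  configs <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- lapply(seq_len(d), function(j) axes[[j]][[combos[i, j]]])
    names(cfg) <- vapply(space, `[[`, "", "name")
    cfg
  })
  configs[seq_len(min(length(configs), budget))]
}

# Gaussian-process surrogate with a squared-exponential kernel on the
# unit-scaled space; candidates scored by expected improvement.
gp_propose <- function(U, yobs, space, n_cand = 256) {
  d <- ncol(U)
  ls <- 0.3
  k <- function(A, B) {
    D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-pmax(D, 0) / (2 * ls^2))
  }
  ymu <- mean(yobs); ysd <- max(sd(yobs), 1e-8)
  ys <- (yobs - ymu) / ysd
  K <- k(U, U) + diag(1e-6 + 1e-4, nrow(U))
  Kinv_y <- solve(K, ys)
  cand <- matrix(runif(n_cand * d), n_cand, d)
  Kc <- k(cand, U)
  mu <- as.numeric(Kc %*% Kinv_y)
  var <- pmax(1 - rowSums(Kc * t(solve(K, t(Kc)))), 1e-10)
  sdv <- sqrt(var)
  best <- min(ys)
  z <- (best - mu) / sdv
  ei <- sdv * (z * pnorm(z) + dnorm(z))
  cand[which.max(ei), ]
}

# Tree-structured Parzen estimator step: split observed trials into good
# (best gamma quantile) and bad, sample candidates around good points, and
# keep the candidate maximizing the good/bad density ratio per dimension.
tpe_propose <- function(U, yobs, space, gamma = 0.25, n_cand = 24) {
  d <- ncol(U)
  n_good <- max(1, ceiling(gamma * nrow(U)))
  ord <- order(yobs)
  good <- U[ord[seq_len(n_good)], , drop = FALSE]
  bad <- U[ord[-seq_len(n_good)], , drop = FALSE]
  if (nrow(bad) == 0) bad <- U
  bw <- 0.2
  # per-dimension kernel density of x under the point set
  dens <- function(pts, x) {
    vapply(seq_len(d), function(j) {
      mean(dnorm(x[j] - pts[, j], sd = bw))
    }, numeric(1)) + 1e-12
  }
  best_cand <- NULL; best_ratio <- -Inf
  for (c in seq_len(n_cand)) {
    center <- good[sample.int(nrow(good), 1), ]
    x <- pmin(1, pmax(0, rnorm(d, center, bw)))
    ratio <- sum(log(dens(good, x))) - sum(log(dens(bad, x)))
    if (ratio > best_ratio) {
      best_ratio <- ratio
      best_cand <- x
    }
  }
  best_cand
}

#' Search hyperparameters with a chosen engine and objective
#'
#' `grid` exhaustively evaluates a discretized space (the budget caps the
#' grid), `bayes` runs sequential model-based optimization with a
#' Gaussian-process surrogate and expected-improvement acquisition, and
#' `tpe` runs a tree-structured Parzen estimator sampler. All engines are
#' deterministic for a fixed seed and return the trial attaining the
#' minimum objective.
#'
#' @param engine One of `"grid"`, `"bayes"`, `"tpe"`.
#' @param spec A [model_spec()] naming the algorithm (its hyperparameters
#'   act as fixed values for dimensions not in `space`).
#' @param split A `ds_split` with train and validation partitions.
#' @param objective_name One of `"hamming"`, `"kappa_mcc_error"`,
#'   `"custom_score"`.
#' @param budget Total number of trials (>= 1).
#' @param seed Integer seed.
#' @param space Search space (list of [param_num()]/[param_int()]/
#'   [param_cat()]); defaults to [default_search_space()] for the
#'   algorithm.
#' @param class_weight Positive-class weight forwarded to every fit.
#' @return A list with `best` (the best `trial_record`),
#'   `best_hyperparameters`, and `trials` (all records, in order).
#' @export
search_hyperparameters <- function(engine = c("grid", "bayes", "tpe"),
                                   spec, split, objective_name,
                                   budget = 50, seed = 1, space = NULL,
                                   class_weight = 1) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "model_spec"))
  if (budget < 1) stop("budget must be at least 1", call. = FALSE)
  space <- space %||% default_search_space(spec$name)
  if (length(space) == 0) stop("empty search space", call. = FALSE)

  eval_cfg <- function(cfg, trial_i) {
    trial_spec <- model_spec(
      spec$name, utils::modifyList(spec$hyperparameters, cfg))
    objective_value(trial_spec, split, objective_name,
                    class_weight = class_weight,
                    seed = child_seed(seed, 1000L + trial_i))
  }

  trials <- list()
  if (engine == "grid") {
    configs <- with_seed(seed, grid_configs(space, budget))
    for (i in seq_along(configs)) {
      trials[[i]] <- eval_cfg(configs[[i]], i)
    }
  } else {
    d <- length(space)
    n_init <- min(budget, max(4, d + 1))
    U <- matrix(NA_real_, 0, d)
    with_seed(seed, {
      for (i in seq_len(budget)) {
        u <- if (i <= n_init) {
          runif(d)
        } else {
          yobs <- vapply(trials, `[[`, 0, "objective_value")
          ok <- is.finite(yobs)
          if (sum(ok) < 2) runif(d)
          else if (engine == "bayes") {
            gp_propose(U[ok, , drop = FALSE], yobs[ok], space)
          } else {
            tpe_propose(U[ok, , drop = FALSE], yobs[ok], space)
          }
        }
        cfg <- lapply(seq_len(d), function(j) unit_to_param(space[[j]],
                                                            u[j]))
        names(cfg) <- vapply(space, `[[`, "", "name")
        trials[[i]] <- eval_cfg(cfg, i)
        U <- rbind(U, u)
      }
    })
  }
  vals <- vapply(trials, `[[`, 0, "objective_value")
  if (all(!is.finite(vals))) {
    stop("every trial failed; check the model/backend", call. = FALSE)
  }
  best_i <- which.min(vals)
  list(best = trials[[best_i]],
       best_hyperparameters = trials[[best_i]]$hyperparameters,
       trials = trials)
}
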
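test_that("normalizers reproduce the textbook transforms", {
  X <- matrix(c(0, 5, 10), 3, 1, dimnames = list(NULL, "f"))
  st <- fit_normalizer(X, "minmax")
  expect_equal(as.numeric(apply_normalizer(st, X)), c(0, 0.5, 1))

  # population-SD convention: column (1, 3) standardizes to (-1, +1)
  X2 <- matrix(c(1, 3), 2, 1, dimnames = list(NULL, "f"))
  st2 <- fit_normalizer(X2, "standard")
  expect_equal(as.numeric(apply_normalizer(st2, X2)), c(-1, 1))

  st3 <- fit_normalizer(X, "none")
  expect_identical(apply_normalizer(st3, X), X)

  # out-of-range test values are not clipped: 20 with train (0,10) -> 2
  Xtest <- matrix(20, 1, 1, dimnames = list(NULL, "f"))
  expect_equal(as.numeric(apply_normalizer(st, Xtest)), 2)

  # zero-range features map to 0
  Xc <- cbind(f = c(0, 5, 10), flat = c(2, 2, 2))
  stc <- suppressMessages(fit_normalizer(Xc, "minmax"))
  expect_true(all(apply_normalizer(stc, Xc)[, "flat"] == 0))

  bad <- matrix(1:3, 3, 1, dimnames = list(NULL, "other"))
  expect_error(apply_normalizer(st, bad), "does not match")
})

test_that("normalizer application is idempotently consistent with fitting", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (m in c("minmax", "standard")) {
    st <- fit_normalizer(X, m)
    t1 <- apply_normalizer(st, X)
    t2 <- apply_normalizer(st, X)
    expect_identical(t1, t2)
    if (m == "minmax") expect_true(all(t1 >= 0 & t1 <= 1))
    if (m == "standard") expect_equal(colMeans(t1), c(a = 0, b = 0, c = 0))
  }
})

test_that("resampling reaches class parity and 'none' attaches the weight", {
  set.seed(11)
  X <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(sprintf("s%d", 1:100), paste0("f", 1:4)))
  y <- c(rep(0L, 80), rep(1L, 20))

  un <- resample(X, y, "undersample", seed = 1)
  expect_equal(as.numeric(table(un$y)), c(20, 20))
  expect_equal(un$class_weight, 1)

  ov <- resample(X, y, "oversample", seed = 1)
  expect_equal(as.numeric(table(ov$y)), c(80, 80))
  # oversampling only duplicates existing minority rows
  expect_true(all(duplicated(rbind(X[y == 1, ], ov$X[ov$y == 1, ]))[-(1:20)]))

  sm <- suppressMessages(resample(X, y, "smote", seed = 1))
  expect_equal(as.numeric(table(sm$y)), c(80, 80))

  no <- resample(X, y, "none", seed = 1)
  expect_identical(no$X, X)
  expect_identical(no$y, y)
  expect_equal(no$class_weight, 4.0)

  expect_error(resample(X, rep(0L, 100), "none"), "both classes")
})

test_that("SMOTE synthesizes points on segments between minority neighbours", {
  # minority rows live exactly on the line f2 = 2 * f1; any interpolation
  # between minority points must preserve that relation.
  set.seed(2)
  n_min <- 12
  f1 <- rnorm(n_min)
  Xmin <- cbind(f1 = f1, f2 = 2 * f1)
  Xmaj <- cbind(f1 = rnorm(40, 5), f2 = rnorm(40, -5))
  X <- rbind(Xmin, Xmaj)
  rownames(X) <- sprintf("s%d", seq_len(nrow(X)))
  y <- c(rep(1L, n_min), rep(0L, 40))
  sm <- resample(X, y, "smote", seed = 3)
  synth <- sm$X[grepl("^smote_", rownames(sm$X)), , drop = FALSE]
  expect_equal(nrow(synth), 40 - n_min)
  expect_equal(synth[, "f2"], 2 * synth[, "f1"], tolerance = 1e-10,
               ignore_attr = TRUE)
  # synthetic rows stay inside the minority bounding box
  expect_true(all(synth[, "f1"] >= min(f1) & synth[, "f1"] <= max(f1)))
})
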
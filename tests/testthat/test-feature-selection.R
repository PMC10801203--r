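test_that("variance and MAD filters follow their definitions", {
  X <- cbind(flat = rep(1, 9), mid = rep(c(-1, 0, 1), 3) * 1,
             wide = rep(c(-2, 0, 2), 3))
  expect_setequal(hvf_select(X, 2), c("wide", "mid"))
  expect_setequal(hvf_select(X, 3), colnames(X))
  expect_error(hvf_select(X, 4), "exceeds")
  # tie-break by input order on a constant matrix
  Xc <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(hvf_select(Xc, 2), c("a", "b"))

  # MADs (0, small, large, larger): median-exceeders survive
  Xm <- cbind(m0 = rep(0, 11), m1 = seq(-1, 1, length.out = 11),
              m2 = seq(-2, 2, length.out = 11),
              m3 = seq(-3, 3, length.out = 11))
  expect_setequal(median_mad_select(Xm), c("m2", "m3"))
  expect_warning(all_back <- median_mad_select(Xc), "equal MAD")
  expect_equal(all_back, colnames(Xc))
  # one dominant-spread feature among constants
  Xd <- cbind(flat1 = rep(2, 11), flat2 = rep(3, 11),
              spread = seq(-5, 5, length.out = 11))
  expect_equal(median_mad_select(Xd), "spread")
})

test_that("correlation pruning removes the later feature of offending pairs", {
  set.seed(4)
  x <- rnorm(100)
  X <- cbind(a = x, b = rnorm(100), dup_a = x)
  kept <- remove_high_corr(X, 0.9)
  expect_equal(kept, c("a", "b"))   # the later duplicate is dropped

  blocks <- make_correlated_block(n = 2000, block = 10, r = 0.95,
                                  seed = 9, n_blocks = 3)
  surv <- remove_high_corr(blocks$X, 0.9)
  expect_length(surv, 3)            # one survivor per block
  cm <- abs(cor(blocks$X[, surv]))
  expect_true(all(cm[upper.tri(cm)] <= 0.9))

  ortho <- make_correlated_block(n = 3000, block = 6, r = 0, seed = 10)
  expect_equal(remove_high_corr(ortho$X, 0.9), colnames(ortho$X))
  expect_error(remove_high_corr(X, 0), "\\(0, 1\\]")
})

test_that("unsupervised reducers find structure and are seed-deterministic", {
  # one feature carries (almost) all the variance: SelByPCA k=1 finds it
  set.seed(12)
  z <- rnorm(300)
  Xp <- cbind(carrier = 10 * z, n1 = rnorm(300, sd = 0.05),
              n2 = rnorm(300, sd = 0.05))
  expect_equal(unsupervised_select(Xp, "SelByPCA", 1), "carrier")

  # three separated feature groups: clustering takes one rep per group
  gens <- lapply(1:3, function(g) {
    base <- rnorm(200)
    sapply(1:4, function(i) base + rnorm(200, sd = 0.1))
  })
  Xg <- do.call(cbind, gens)
  colnames(Xg) <- sprintf("grp%d_f%d", rep(1:3, each = 4), rep(1:4, 3))
  reps <- unsupervised_select(Xg, "SelByClustering", 3, seed = 2)
  expect_setequal(substr(reps, 1, 4), c("grp1", "grp2", "grp3"))

  for (m in c("SelByPCA", "RandomProjection", "SelByClustering",
              "SelByNMF")) {
    s1 <- unsupervised_select(Xg, m, 3, seed = 5)
    s2 <- unsupervised_select(Xg, m, 3, seed = 5)
    expect_identical(s1, s2)
    expect_length(s1, 3)
    expect_true(all(s1 %in% colnames(Xg)))
  }
})

test_that("supervised selectors recover a planted separating feature", {
  set.seed(30)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(NULL, sprintf("f%02d", 1:50)))
  X[, "f25"] <- ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.3)
  for (m in c("SelectByRF", "RecursiveFeatElim", "SeqFeatSel")) {
    expect_equal(supervised_select(X[, c(1:10, 25)], y, m, k = 1,
                                   seed = 3, num_trees = 200), "f25",
                 label = m)
  }
  # k = p is the identity set
  expect_setequal(supervised_select(X[, 1:5], y, "SelectByRF", k = 5,
                                    seed = 1), colnames(X)[1:5])
  expect_error(supervised_select(X, rep(1L, n), "SelectByRF", k = 2),
               "both classes")
})

test_that("exhaustive subset search equals an independent enumeration", {
  set.seed(40)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("v%d", 1:6)))
  X[, "v3"] <- ifelse(y == 1, 2.5, -2.5) + rnorm(n, sd = 0.2)
  scorer <- function(X, y, features, seed) {
    drugsense:::cv_subset_score(X, y, features, seed = seed)
  }
  got <- iterative_select(X, y, max_size = 2, seed = 5)
  # independent re-enumeration over all size-1 and size-2 subsets
  subsets <- c(as.list(colnames(X)),
               combn(colnames(X), 2, simplify = FALSE))
  scores <- vapply(subsets, function(s) scorer(X, y, s, 5), numeric(1))
  expect_identical(got, subsets[[which.min(scores)]])
  expect_equal(got, "v3")

  # XOR pair: only jointly informative
  set.seed(41)
  a <- sample(c(-1, 1), 200, replace = TRUE)
  b <- sample(c(-1, 1), 200, replace = TRUE)
  yx <- as.integer(a * b > 0)
  Xx <- cbind(a = a + rnorm(200, sd = 0.1), b = b + rnorm(200, sd = 0.1),
              junk1 = rnorm(200), junk2 = rnorm(200))
  expect_setequal(iterative_select(Xx, yx, max_size = 2, seed = 6),
                  c("a", "b"))

  big <- matrix(rnorm(40 * 60), 40, 60,
                dimnames = list(NULL, sprintf("g%d", 1:60)))
  expect_error(iterative_select(big, rep(0:1, 20), max_size = 3),
               "cap")
})

test_that("chains preserve subset monotonicity and handle None/diagnostics", {
  gen <- make_classification_data(
    synth_spec(n_samples = 120, n_features = 60, n_informative = 4,
               seed = 13))
  chain <- list(selection_step("HVF", k = 40),
                selection_step("SelectByRF", k = 10, seed = 2),
                selection_step("SelByPCA", k = 5, seed = 3),
                selection_step("IterativeFeatSel",
                               params = list(max_size = 2), seed = 4))
  res <- run_chain(chain, gen$dataset)
  expect_equal(res$per_step$n_in, c(60, 40, 10, 5))
  expect_true(all(res$per_step$n_out <= res$per_step$n_in))
  expect_true(all(res$selected %in% gen$dataset$feature_names))

  idres <- run_chain(list(selection_step("None"), selection_step("None")),
                     gen$dataset)
  expect_equal(idres$selected, gen$dataset$feature_names)

  unl <- new_dataset(gen$dataset$X)
  expect_error(run_chain(list(selection_step("SelectByRF", k = 5)), unl),
               "require labels")
  expect_error(selection_step("Bogus"), "unknown selection method")
  expect_error(run_chain(as.list(rep(list(selection_step("None")), 5)),
                         gen$dataset), "at most 4")
})
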
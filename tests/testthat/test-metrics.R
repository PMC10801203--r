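test_that("confusion counts and the seven losses match worked arithmetic", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L),
               ignore_attr = TRUE)

  mv <- loss_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0),
                     c(0.9, 0.1, 0.9, 0.1))
  expect_equal(unname(mv),
               c(0.5, 1.0, 0.5, 0.5, 0.5, 0.5, 0.41))

  perfect <- loss_metrics(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  expect_equal(unname(perfect), rep(0, 7))

  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(loss_metrics(c(1, 0), c(1, 0), c(1.2, 0)), "\\[0,1\\]")
})

test_that("composite score matches the documented RMS/geometric-mean form", {
  cs <- composite_score(rep(0, 7), rep(0.5, 7))
  expect_equal(cs$D, 0.5)
  expect_equal(cs$L, 0.5)

  cs2 <- composite_score(rep(0.5, 7), rep(0.5, 7))  # D = 0, L = 0.5
  expect_equal(cs2$D, 0)
  expect_equal(cs2$neglog2rmsl, -log2(sqrt(0.025)), tolerance = 1e-12)
  expect_equal(round(cs2$neglog2rmsl, 4), 2.661)

  # (D + 0.05) = 1 and L = 1 gives exactly 0
  cs3 <- composite_score(rep(0.95 + 1, 7) / 1, rep(1, 7))
  expect_equal(cs3$neglog2rmsl, 0)
  expect_error(composite_score(rep(0, 6), rep(0, 7)), "length 7")
})

test_that("KME and custom_score follow the clipped geometric-mean formulas", {
  expect_equal(kappa_mcc_error(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  # chance-level: orthogonal predictions
  expect_equal(kappa_mcc_error(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1)
  # worse than chance clips to 1
  expect_equal(kappa_mcc_error(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # spot value: kappa=0.81, mcc=0.64 -> 1 - sqrt(0.5184) = 0.28
  expect_equal(1 - sqrt(0.81 * 0.64), 0.28, tolerance = 1e-12)

  expect_equal(custom_score(0, 0), 0)
  expect_equal(custom_score(0.1, 0.3), 0.06, tolerance = 1e-12)
  expect_equal(custom_score(0.3, 0.3), 0)
  expect_equal(custom_score(0.3, 0.1), custom_score(0.1, 0.3) / 3,
               tolerance = 1e-12)  # |a-b| symmetric, scaled by kme_test
  expect_error(custom_score(1.2, 0.3), "\\[0,1\\]")
})

test_that("scoring core agrees with the brute-force oracle on 1000 instances", {
  set.seed(101)
  for (i in 1:1000) {
    inst <- random_instance(sample(4:40, 1))
    mv <- loss_metrics(inst$y, inst$pred, inst$prob)
    expect_equal(unname(mv), oracle_loss_metrics(inst$y, inst$pred,
                                                 inst$prob),
                 tolerance = 1e-12)
    expect_equal(kappa_mcc_error(inst$y, inst$pred),
                 oracle_kme(inst$y, inst$pred), tolerance = 1e-12)
    expect_true(all(mv >= 0 & mv <= 1))
  }
})

test_that("NegLog2RMSL is monotone decreasing in D and L", {
  L_grid <- seq(0.05, 1, by = 0.05)
  nl_L <- vapply(L_grid, function(L)
    -log2(sqrt((0.2 + 0.05) * L)), numeric(1))
  expect_true(all(diff(nl_L) < 0))
  D_grid <- seq(0, 1, by = 0.05)
  nl_D <- vapply(D_grid, function(D)
    -log2(sqrt((D + 0.05) * 0.4)), numeric(1))
  expect_true(all(diff(nl_D) < 0))
})

test_that("score normalization is rank-preserving with degenerate handling", {
  expect_equal(normalize_scores(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(suppressMessages(normalize_scores(c(2, 2, 2))),
               rep(0.5, 3))
  set.seed(5)
  x <- rnorm(20)
  expect_equal(order(normalize_scores(x)), order(x))
  expect_error(normalize_scores(3), "at least 2")
  expect_error(normalize_scores(c(1, Inf)), "finite")
})
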
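test_that("CSV datasets load with label encoding and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2,g3,response",
               "s1,1.5,0.2,3.0,sensitive",
               "s2,0.1,0.4,2.0,resistant",
               "s3,2.5,0.1,1.0,sensitive",
               "s4,0.3,0.9,0.5,resistant"), path)
  ds <- load_csv_dataset(path, "response", "sensitive")
  expect_equal(ds$y, c(1L, 0L, 1L, 0L))
  expect_equal(ds$feature_names, c("g1", "g2", "g3"))
  expect_equal(ds$sample_ids, c("s1", "s2", "s3", "s4"))
  expect_equal(ds$X["s3", "g1"], 2.5)

  rt <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, rt, label_column = "response",
                    negative_label = "resistant")
  ds2 <- load_csv_dataset(rt, "response", "sensitive")
  expect_identical(ds2$X, ds$X)
  expect_identical(ds2$y, ds$y)
  expect_identical(ds2$feature_names, ds$feature_names)
})

test_that("degenerate and malformed inputs are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,response", "1,2,sensitive", "3,4,sensitive"), path)
  expect_error(load_csv_dataset(path, "response", "sensitive"),
               "degenerate labels")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,tissue,response", "1,brain,sensitive",
               "3,lung,resistant"), path2)
  expect_error(load_csv_dataset(path2, "response", "sensitive"), "tissue")

  expect_error(load_csv_dataset("no/such/file.csv", "y", "a"),
               "not found")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,response", "1,a", "2,b", "3,c"), path3)
  expect_error(load_csv_dataset(path3, "response", "a"), "binary")
})

test_that("cleaning replaces missing cells with zero and reports the count", {
  X <- matrix(c(1, NA, 3, NaN, 5, NA), 2, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ds <- new_dataset(X, c(0, 1))
  cleaned <- suppressMessages(clean_dataset(ds))
  expect_equal(attr(cleaned, "n_cleaned"), 3)
  expect_equal(sum(cleaned$X == 0), 3)
  expect_false(anyNA(cleaned$X))

  # no-missing input is bit-identical
  ds_ok <- new_dataset(matrix(1:4 / 2, 2, 2), c(0, 1))
  expect_identical(clean_dataset(ds_ok)$X, ds_ok$X)

  # all-missing input becomes all zero with a warning
  ds_bad <- new_dataset(matrix(NA_real_, 2, 2), c(0, 1))
  expect_warning(out <- suppressMessages(clean_dataset(ds_bad)),
                 "all feature values")
  expect_true(all(out$X == 0))
})

test_that("stratified split honors class proportions and is deterministic", {
  gen <- make_classification_data(
    synth_spec(n_samples = 100, n_features = 5, n_informative = 1,
               class_balance = 0.2, seed = 3))
  ds <- gen$dataset
  sp <- stratified_split(ds, 0.2, seed = 1)
  expect_equal(nrow(sp$test$X), 20)
  expect_equal(sum(sp$test$y == 1), 4)   # 20% of the 20 positives
  expect_equal(sum(sp$test$y == 0), 16)

  sp2 <- stratified_split(ds, 0.2, seed = 1)
  expect_identical(sp$test$sample_ids, sp2$test$sample_ids)

  # disjointness and coverage
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids),
                  ds$sample_ids)

  expect_error(stratified_split(ds, 0, seed = 1), "strictly between")
  tiny <- new_dataset(matrix(rnorm(6), 3, 2), c(1, 0, 0))
  expect_error(stratified_split(tiny, 0.3, seed = 1), "at least 2")
})
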
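# Importance ranking, correlations, classifier evaluation.

make_features <- function(mat, ids) {
  df <- data.frame(sample_id = ids, mat, stringsAsFactors = FALSE)
  names(df)[-1] <- feature_names()
  df
}

# linearly separable 3-class fixture: class means at simplex corners (one
# indicator dimension per class), so every one-vs-rest problem is separable
separable_dataset <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(0:2, each = n_per_class)
    x <- matrix(rnorm(3 * n_per_class * 16), ncol = 16)
    x[, 2] <- 6 * (cls == 0) + rnorm(length(cls))
    x[, 5] <- 6 * (cls == 1) + rnorm(length(cls))
    x[, 11] <- 6 * (cls == 2) + rnorm(length(cls))
    ids <- sprintf("s%03d", seq_along(cls))
    k <- 10^(6 - cls)
    assemble_dataset(make_features(x, ids),
                     data.frame(sample_id = ids, k = k, rate_class = cls))
  })
}

# class a monotone function of X5 alone, with wide gaps
x5_dataset <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(0:2, each = n_per_class)
    x <- matrix(rnorm(3 * n_per_class * 16), ncol = 16)
    x[, 5] <- cls * 10 + rnorm(length(cls), 0, 0.1)
    ids <- sprintf("s%03d", seq_along(cls))
    assemble_dataset(make_features(x, ids),
                     data.frame(sample_id = ids, k = 10^(6 - cls),
                                rate_class = cls))
  })
}

test_that("dataset assembly joins on sample_id and rejects bad input", {
  ds <- separable_dataset()
  expect_s3_class(ds, "labeled_dataset")
  expect_identical(nrow(ds), 60L)
  f <- make_features(matrix(0, 3, 16), c("a", "b", "c"))
  r <- data.frame(sample_id = c("x", "y", "z"), k = 1, rate_class = 0)
  expect_error(assemble_dataset(f, r), "orphan")
  r2 <- data.frame(sample_id = c("a", "b", "b"), k = 1, rate_class = 0)
  expect_error(assemble_dataset(f, r2), "duplicate")
  # join is order-invariant
  r3 <- data.frame(sample_id = c("c", "a", "b"), k = 1:3, rate_class = c(0, 1, 2))
  d1 <- assemble_dataset(f, r3)
  d2 <- assemble_dataset(f[c(2, 3, 1), ], r3[c(3, 1, 2), ])
  expect_identical(d1, d2)
})

test_that("random-forest importance recovers a planted single-feature signal", {
  ds <- x5_dataset(n_per_class = 30)
  top <- vapply(1:10, function(s) feature_importance(ds, seed = s)$feature[1],
                character(1))
  expect_gte(sum(top == "X5"), 9)
  imp <- feature_importance(ds, seed = 1)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$weight) <= 0))
  # a constant feature carries (almost) no importance
  ds$X9 <- 0
  imp2 <- feature_importance(ds, seed = 1)
  expect_lt(imp2$weight[imp2$feature == "X9"], 0.01)
  one_class <- ds[ds$rate_class == 0, ]
  expect_error(feature_importance(one_class), "2 classes")
})

test_that("Pearson correlations behave on planted linear structure", {
  ds <- x5_dataset()
  pc <- pearson_correlations(ds)
  expect_equal(diag(pc), setNames(rep(1, 17), colnames(pc)))
  expect_equal(pc, t(pc))
  # X5 increases with class while k decreases: strong negative correlation
  expect_lt(pc["X5", "log10_k"], -0.9)
  # planted y = 2x + noise
  n <- 100
  x <- matrix(rnorm(16 * n), ncol = 16)
  x[, 2] <- 2 * x[, 1] + rnorm(n, 0, 0.3)
  ds2 <- assemble_dataset(make_features(x, sprintf("m%03d", 1:n)),
                          data.frame(sample_id = sprintf("m%03d", 1:n),
                                     k = 1e5, rate_class = 0))
  expect_gt(pearson_correlations(ds2, include_k = FALSE)["X1", "X2"], 0.9)
  # zero-variance column reported as missing (off the trivial diagonal)
  ds2$X16 <- 1
  col <- pearson_correlations(ds2, include_k = FALSE)[, "X16"]
  expect_true(all(is.na(col[names(col) != "X16"])))
})

test_that("all classifiers are perfect on a separable fixture", {
  ds <- separable_dataset(n_per_class = 25)
  for (ms in c("logistic_regression", "svm", "decision_tree")) {
    rep <- train_and_evaluate(ds, ms, seed = 3)
    expect_equal(rep$val_accuracy, 1.0)
    expect_true(all(rep$auc_per_class == 1))
    expect_equal(rep$auc_micro, 1.0)
    expect_equal(rep$auc_macro, 1.0)
    expect_true(all(rep$auc_per_class >= 0 & rep$auc_per_class <= 1))
    # confusion rows sum to validation class counts
    expect_identical(sum(rep$confusion), as.integer(rep$n_val))
  }
})

test_that("evaluation reports are byte-identical across reruns", {
  ds <- planted_dataset(80, seed = 4)
  r1 <- train_and_evaluate(ds, "svm", seed = 9)
  r2 <- train_and_evaluate(ds, "svm", seed = 9)
  expect_identical(r1, r2)
  i1 <- feature_importance(ds, seed = 9)
  expect_identical(i1, feature_importance(ds, seed = 9))
})

test_that("removing an all-constant feature does not change tree accuracy", {
  ds <- separable_dataset(n_per_class = 20, seed = 6)
  ds$X12 <- 7
  r1 <- train_and_evaluate(ds, "decision_tree", seed = 2)
  ds2 <- ds
  ds2$X12 <- 0
  r2 <- train_and_evaluate(ds2, "decision_tree", seed = 2)
  expect_identical(r1$val_accuracy, r2$val_accuracy)
})

test_that("external test reproduces training accuracy on copied rows", {
  ds <- separable_dataset(n_per_class = 15, seed = 8)
  res <- external_test(ds, ds, model_specs = "decision_tree", seed = 1)
  expect_equal(unname(res$accuracy["decision_tree"]), 1.0)
  expect_identical(nrow(res$predictions), nrow(ds))
})

test_that("external test predicts planted in-distribution samples and flags lengths", {
  big <- planted_dataset(120, seed = 10)
  big$invader_len <- 22L
  tr <- big[1:104, ]
  te <- big[105:120, ]
  te$invader_len[1:3] <- 20L
  res <- external_test(tr, te, seed = 2)
  expect_gte(max(res$accuracy), 0.8)
  expect_identical(res$predictions$length_mismatch,
                   c(rep(TRUE, 3), rep(FALSE, 13)))
  # schema mismatch refused
  bad <- te
  names(bad)[names(bad) == "X16"] <- "Z16"
  expect_error(external_test(tr, bad), "schema")
})
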
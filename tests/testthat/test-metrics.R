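test_that("confusion matrix tabulates true-by-predicted counts", {
  M <- confusion_matrix(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 3, 1), 3)
  expect_identical(M, matrix(c(1L, 0L, 1L, 1L, 2L, 0L, 0L, 0L, 1L), 3, 3))
  expect_identical(sum(M), 6L)

  perfect <- confusion_matrix(1:4, 1:4, 4)
  expect_identical(perfect, diag(1L, 4L) + matrix(0L, 4, 4))

  expect_error(confusion_matrix(integer(0), integer(0), 3), "empty")
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 3), "range")
})

test_that("metric suite matches hand evaluation and the diagonal case", {
  M <- confusion_matrix(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 3, 1), 3)
  r <- metrics_from_confusion(M)
  expect_equal(r$per_class$precision, c(1/2, 2/3, 1))
  expect_equal(r$per_class$recall, c(1/2, 1, 1/2))
  expect_equal(r$accuracy, 4 / 6)

  d <- metrics_from_confusion(diag(5L, 4L))
  expect_equal(c(d$precision, d$recall, d$f1, d$accuracy), rep(1, 4))

  # class absent from truth and prediction: 0/0 convention, with warning
  M2 <- matrix(0L, 3, 3); M2[1, 1] <- 2L; M2[2, 2] <- 2L
  expect_warning(r2 <- metrics_from_confusion(M2), "0/0")
  expect_equal(r2$per_class$precision[3], 0)
  expect_equal(r2$per_class$f1[3], 0)

  expect_error(metrics_from_confusion(matrix(0L, 3, 3)), "all-zero")
})

test_that("metrics agree with a brute-force tally on random label vectors", {
  set.seed(20)
  for (i in 1:50) {
    K <- sample(2:10, 1)
    n <- sample(10:300, 1)
    y_true <- sample.int(K, n, replace = TRUE)
    y_pred <- sample.int(K, n, replace = TRUE)
    M <- confusion_matrix(y_true, y_pred, K)
    got <- suppressWarnings(metrics_from_confusion(M))
    want <- metrics_oracle(y_true, y_pred, K)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$per_class$f1, want$per_class_F1)
  }
})

test_that("metrics agree with caret's independent computation", {
  skip_if_not_installed("caret")
  set.seed(21)
  y_true <- sample.int(5, 200, replace = TRUE)
  y_pred <- sample.int(5, 200, replace = TRUE)
  cm <- caret::confusionMatrix(factor(y_pred, levels = 1:5),
                               factor(y_true, levels = 1:5))
  got <- suppressWarnings(
    metrics_from_confusion(confusion_matrix(y_true, y_pred, 5)))
  expect_equal(got$accuracy, unname(cm$overall["Accuracy"]))
  expect_equal(got$per_class$recall, unname(cm$byClass[, "Sensitivity"]))
  expect_equal(got$per_class$precision, unname(cm$byClass[, "Precision"]))
})

test_that("permuting class indices permutes per-class but fixes macro metrics", {
  set.seed(22)
  y_true <- sample.int(6, 300, replace = TRUE)
  y_pred <- sample.int(6, 300, replace = TRUE)
  M <- confusion_matrix(y_true, y_pred, 6)
  r <- suppressWarnings(metrics_from_confusion(M))
  perm <- sample.int(6)
  Mp <- confusion_matrix(perm[y_true], perm[y_pred], 6)
  rp <- suppressWarnings(metrics_from_confusion(Mp))
  expect_equal(rp$per_class$f1[perm], r$per_class$f1)
  expect_equal(rp$precision, r$precision)
  expect_equal(rp$f1, r$f1)
  expect_equal(rp$accuracy, r$accuracy)
})

test_that("per-crop aggregation follows the 22-class grouping", {
  man <- leaf_disease_manifest()
  groups <- man$crop
  expect_identical(length(groups), 22L)
  counts <- table(groups)
  expect_equal(as.integer(counts[c("Apple", "Bean", "Maize", "Strawberry",
                                   "Sugarcane", "Wheat")]),
               c(7L, 3L, 4L, 2L, 3L, 3L))
  expect_identical(sum(counts), 22L)

  # identity predictions: every crop scores 1
  M <- diag(3L, 22L)
  pg <- per_group_metrics(M, groups)
  expect_equal(pg$f1, rep(1, 6))
  expect_equal(pg$precision, rep(1, 6))

  # a single all-encompassing group reproduces the global macro metrics
  set.seed(23)
  y_true <- sample.int(4, 100, replace = TRUE)
  y_pred <- sample.int(4, 100, replace = TRUE)
  M4 <- confusion_matrix(y_true, y_pred, 4)
  r <- suppressWarnings(metrics_from_confusion(M4))
  pg1 <- suppressWarnings(per_group_metrics(M4, rep("all", 4)))
  expect_equal(pg1$precision, r$precision)
  expect_equal(pg1$f1, r$f1)

  expect_error(per_group_metrics(M4, c("a", "b", NA, "c")), "map")
  expect_error(per_group_metrics(M4, c("a", "b")), "map")
})
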
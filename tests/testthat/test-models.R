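# Hand-built splits around well-separated Gaussian blobs: class 1 near the
# origin, class 0 shifted by `sep` on every coordinate.
blob_split <- function(mode = "multi_class", n = 40, p = 4, sep = 6,
                       seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(n * p), n, p)
  neg <- matrix(rnorm(n * p, mean = sep), n, p)
  colnames(pos) <- colnames(neg) <- paste0("f", seq_len(p))
  test_x <- rbind(
    matrix(rnorm(10 * p), 10, p),
    matrix(rnorm(10 * p, mean = sep), 10, p)
  )
  colnames(test_x) <- colnames(pos)
  test <- list(
    x = test_x, y = c(rep(1L, 10), rep(0L, 10)),
    ids = paste0("t", 1:20)
  )
  if (mode == "multi_class") {
    structure(
      list(
        user_id = "u", mode = mode, seed = seed,
        train = list(
          x = rbind(pos, neg), y = rep(c(1L, 0L), each = n),
          ids = paste0("r", seq_len(2 * n))
        ),
        val = NULL, test = test
      ),
      class = "split_bundle"
    )
  } else {
    structure(
      list(
        user_id = "u", mode = mode, seed = seed,
        train = list(x = pos, y = rep(1L, n), ids = paste0("r", seq_len(n))),
        val = NULL, test = test
      ),
      class = "split_bundle"
    )
  }
}

test_that("classifier specs validate fields and bounds", {
  expect_error(classifier_spec("rf", nu = 0.3), "not relevant")
  expect_error(classifier_spec("oc_svm", nu = 1.5), "nu")
  expect_error(classifier_spec("iforest", contamination = 0.7), "contamination")
  spec <- classifier_spec("svm")
  expect_equal(spec$C_grid, c(0.1, 1, 10, 100, 1000))
  expect_equal(length(spec$gamma_grid), 8)
  expect_equal(spec$cv_folds, 10)
  expect_equal(classifier_spec("rf")$n_estimators, 500)
  expect_equal(classifier_spec("knn")$k_neighbors, 25)
})

test_that("a random forest separates two distant blobs perfectly", {
  sp <- blob_split()
  model <- train_model(classifier_spec("rf", n_estimators = 100), sp)
  expect_equal(predict(model, sp$test$x), sp$test$y)
})

test_that("an isolation forest rejects 10-sigma outliers", {
  sp <- blob_split(mode = "one_class", sep = 0)
  model <- train_model(
    classifier_spec("iforest", contamination = 0.3, n_estimators = 200), sp
  )
  inliers <- sp$train$x[1:10, , drop = FALSE]
  outliers <- matrix(rnorm(10 * 4, mean = 10), 10, 4)
  colnames(outliers) <- colnames(inliers)
  expect_true(all(predict(model, outliers) == 0))
  expect_gt(mean(predict(model, inliers)), 0.5)
})

test_that("SVM grid search is deterministic and records its choice", {
  sp <- blob_split(n = 30)
  spec <- classifier_spec("svm",
    C_grid = c(0.1, 1), gamma_grid = list("scale", 0.01), cv_folds = 3
  )
  m1 <- train_model(spec, sp)
  m2 <- train_model(spec, sp)
  expect_identical(m1$chosen_hyperparams, m2$chosen_hyperparams)
  expect_true(m1$chosen_hyperparams$C %in% c(0.1, 1))
  expect_equal(predict(m1, sp$test$x), sp$test$y)
})

test_that("all six kinds emit labels in {0, 1}", {
  mc <- blob_split()
  oc <- blob_split(mode = "one_class")
  specs <- list(
    classifier_spec("svm", C_grid = 1, gamma_grid = list("scale"), cv_folds = 2),
    classifier_spec("rf", n_estimators = 50),
    classifier_spec("knn", k_neighbors = 5),
    classifier_spec("oc_svm", nu = 0.2),
    classifier_spec("iforest", n_estimators = 50, contamination = 0.2),
    classifier_spec("lof", k_neighbors = 5, contamination = 0.2)
  )
  for (spec in specs) {
    sp <- if (spec$kind %in% c("svm", "rf", "knn")) mc else oc
    model <- train_model(spec, sp)
    labels <- predict(model, sp$test$x)
    expect_true(all(labels %in% c(0L, 1L)), label = spec$kind)
    expect_length(labels, 20)
    # empty input -> empty output
    empty <- sp$test$x[0, , drop = FALSE]
    expect_length(predict(model, empty), 0)
  }
})

test_that("a 1-NN model memorizes its training labels", {
  sp <- blob_split(sep = 3)
  model <- train_model(classifier_spec("knn", k_neighbors = 1), sp)
  expect_equal(predict(model, sp$train$x), sp$train$y)
})

test_that("one-class kinds demand one-class splits and hide scores", {
  mc <- blob_split()
  oc <- blob_split(mode = "one_class")
  expect_error(
    train_model(classifier_spec("iforest"), mc),
    "one-class split"
  )
  expect_error(train_model(classifier_spec("rf"), oc), "multi-class")
  model <- train_model(classifier_spec("iforest", n_estimators = 50), oc)
  expect_error(predict(model, oc$test$x, type = "score"), "not exposed")
})

test_that("multi-class scores rank the legitimate class higher", {
  sp <- blob_split()
  for (spec in list(
    classifier_spec("rf", n_estimators = 100),
    classifier_spec("knn", k_neighbors = 5),
    classifier_spec("svm", C_grid = 1, gamma_grid = list("scale"), cv_folds = 2)
  )) {
    model <- train_model(spec, sp)
    sc <- predict(model, sp$test$x, type = "score")
    expect_gt(
      mean(sc[sp$test$y == 1]), mean(sc[sp$test$y == 0])
    )
  }
})

test_that("seeded kinds are reproducible and schema mismatches are caught", {
  sp <- blob_split()
  m1 <- train_model(classifier_spec("rf", n_estimators = 50, seed = 3), sp)
  m2 <- train_model(classifier_spec("rf", n_estimators = 50, seed = 3), sp)
  expect_equal(
    predict(m1, sp$test$x, type = "score"),
    predict(m2, sp$test$x, type = "score")
  )
  bad <- sp$test$x
  colnames(bad)[1] <- "zz"
  expect_error(predict(m1, bad), "zz")
})

test_that("raising the rejection budget flags more of the training set", {
  oc <- blob_split(mode = "one_class", n = 60)
  values <- c(0.01, 0.03, 0.05, 0.1, 0.3, 0.5)
  for (kind in c("oc_svm", "iforest", "lof")) {
    flagged <- vapply(values, function(v) {
      spec <- switch(kind,
        oc_svm = classifier_spec("oc_svm", nu = v),
        iforest = classifier_spec("iforest", contamination = v, n_estimators = 100),
        lof = classifier_spec("lof", contamination = v, k_neighbors = 10)
      )
      model <- train_model(spec, oc)
      sum(predict(model, oc$train$x) == 0)
    }, 0)
    if (kind == "oc_svm") {
      # libsvm's nu bounds margin errors in the optimization, not predicted
      # rejections, so small-sample wiggle is expected at low nu; the dial
      # must still clearly open over the sweep
      expect_true(all(diff(flagged) >= -0.1 * 60), label = kind)
      expect_gt(flagged[6], flagged[1])
    } else {
      expect_true(all(diff(flagged) >= 0), label = kind)
    }
  }
})
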
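make_recording <- function(n_samples, n_channels = 14, fs = 256, seed = 1) {
  set.seed(seed)
  eeg_recording(
    "u1", fs, paste0("ch", seq_len(n_channels)),
    matrix(rnorm(n_channels * n_samples), nrow = n_channels)
  )
}

test_that("segmentation arithmetic follows the 240 ms window rule", {
  rec <- make_recording(30720)
  seg <- segment_signal(rec)
  expect_equal(seg$window_samples, 61) # floor(0.240 * 256)
  expect_equal(dim(seg$segments)[1], 503) # floor(30720 / 61)

  expect_equal(dim(segment_signal(make_recording(60))$segments)[1], 0)
})

test_that("segmentation is lossless slicing in order", {
  rec <- make_recording(6100, n_channels = 2)
  seg <- segment_signal(rec)
  expect_equal(dim(seg$segments)[1], 100)
  for (ci in 1:2) {
    rebuilt <- as.numeric(t(seg$segments[, ci, ]))
    expect_equal(rebuilt, unname(rec$signal[ci, 1:6100]))
  }
})

test_that("coefficient metrics match their closed forms", {
  for (c0 in c(3.5, 0)) {
    m <- coefficient_metrics(rep(c0, 4))
    expect_equal(unname(m["max"]), c0)
    expect_equal(unname(m["min"]), c0)
    expect_equal(unname(m["mean"]), c0)
    expect_equal(unname(m["std"]), 0)
    expect_equal(unname(m["var"]), 0)
    expect_equal(unname(m["skewness"]), 0)
    expect_equal(unname(m["shannon_entropy"]), if (c0 == 0) 0 else 2)
    expect_equal(unname(m["avg_power"]), c0^2)
  }
  spike <- coefficient_metrics(c(5, 0, 0, 0))
  expect_equal(unname(spike["shannon_entropy"]), 0)
  expect_equal(unname(spike["max"]), 5)
  expect_equal(unname(spike["avg_power"]), 6.25)
})

test_that("all eight metrics agree with the direct-formula oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(32)
    worst <- max(worst, max(abs(coefficient_metrics(x) - oracle_metrics(x))))
  }
  expect_lt(worst, 1e-10)
})

test_that("feature matrices have channel x band x metric structure", {
  rec <- make_recording(61 * 20)
  fm <- build_feature_matrix(segment_signal(rec))
  expect_equal(ncol(fm$values), 672) # 14 * 6 * 8
  expect_equal(nrow(fm$values), 20)
  expect_false(any(!is.finite(fm$values)))
  expect_equal(nrow(unique(fm$index)), 672)
  # channel-major, then band, then metric
  expect_equal(
    colnames(fm$values)[1:3],
    c("ch1__D1__max", "ch1__D1__min", "ch1__D1__mean")
  )
  expect_equal(colnames(fm$values)[49], "ch2__D1__max")

  one_ch <- build_feature_matrix(segment_signal(make_recording(610, n_channels = 1)))
  expect_equal(ncol(one_ch$values), 48) # 6 * 8

  # identical segments produce identical rows
  rec2 <- eeg_recording("u", 256, "c1", matrix(rep(rnorm(61), 2), nrow = 1))
  fm2 <- build_feature_matrix(segment_signal(rec2))
  expect_equal(fm2$values[1, ], fm2$values[2, ])
})

test_that("band/channel selection keeps |channels| x |waves| x 8 columns", {
  rec <- eeg_recording(
    "u", 256, eegauth:::EEG_CHANNELS,
    matrix(rnorm(14 * 305), nrow = 14)
  )
  fm <- build_feature_matrix(segment_signal(rec))
  expect_equal(ncol(select_features(fm, waves = "D1")$values), 112)
  expect_equal(
    ncol(select_features(fm,
      waves = "D1",
      channels = c("AF3", "P8", "T8", "FC6", "F4")
    )$values),
    40
  )
  expect_equal(
    ncol(select_features(fm,
      waves = c("D1", "D2", "D3"),
      channels = c("AF3", "P8", "T8", "FC6", "F4")
    )$values),
    120
  )
  # identity selection returns the same matrix
  expect_equal(select_features(fm)$values, fm$values)
  expect_error(select_features(fm, waves = "D9"), "D9")
  expect_error(select_features(fm, channels = "XX"), "XX")
})

test_that("metrics transform covariantly under scaling", {
  set.seed(7)
  x <- rnorm(61)
  lambda <- 3.7
  m1 <- coefficient_metrics(x)
  m2 <- coefficient_metrics(lambda * x)
  for (k in c("max", "min", "mean", "std")) {
    expect_equal(unname(m2[k]), lambda * unname(m1[k]))
  }
  for (k in c("var", "avg_power")) {
    expect_equal(unname(m2[k]), lambda^2 * unname(m1[k]))
  }
  for (k in c("skewness", "shannon_entropy")) {
    expect_equal(unname(m2[k]), unname(m1[k]))
  }
})

test_that("permuting channels permutes feature blocks without changing values", {
  set.seed(8)
  sig <- matrix(rnorm(3 * 305), nrow = 3)
  fm1 <- build_feature_matrix(segment_signal(
    eeg_recording("u", 256, c("a", "b", "c"), sig)
  ))
  fm2 <- build_feature_matrix(segment_signal(
    eeg_recording("u", 256, c("c", "a", "b"), sig[c(3, 1, 2), ])
  ))
  expect_equal(
    fm1$values[, colnames(fm1$values)],
    fm2$values[, colnames(fm1$values)]
  )
})

test_that("standardization is train-fitted and guards constant features", {
  set.seed(9)
  train <- cbind(matrix(rnorm(50 * 3), 50, 3), 7) # last column constant
  test <- cbind(matrix(rnorm(20 * 3), 20, 3), 7)
  std <- standardize_features(train, list(test))
  expect_true(all(abs(colMeans(std$train[, 1:3])) < 1e-9))
  expect_true(all(abs(apply(std$train[, 1:3], 2, sd) - 1) < 1e-9))
  expect_true(all(std$train[, 4] == 0))
  expect_true(all(std$others[[1]][, 4] == 0))
  # applying the transform to the train matrix itself reproduces it
  std2 <- standardize_features(train, list(train))
  expect_equal(std2$others[[1]], std2$train)
  expect_error(standardize_features(train[1, , drop = FALSE]), ">= 2 rows")
})

test_that("feature CSV round trip preserves values, index and row metadata", {
  rec <- make_recording(305, n_channels = 2)
  fm <- build_feature_matrix(segment_signal(rec))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back$index, fm$index)
  expect_equal(back$row_meta$user_id, fm$row_meta$user_id)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-12)
})
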
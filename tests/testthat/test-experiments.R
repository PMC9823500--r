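fast_rf <- function(seed = NULL) classifier_spec("rf", n_estimators = 100, seed = seed)
fast_if <- function(v = 0.3) classifier_spec("iforest", n_estimators = 100, contamination = v)

test_that("baseline runs produce per-user and macro-averaged tables", {
  feats <- test_cohort_features(2, 20, seed = 51)
  res <- run_baseline(feats, list(fast_rf(), fast_if()), seed = 1)
  expect_equal(nrow(res$per_user), 4) # 2 users x 2 kinds
  expect_equal(res$summary$kind, c("rf", "iforest"))
  rf_row <- res$summary[res$summary$kind == "rf", ]
  expect_true(all(is.finite(unlist(rf_row[eegauth:::METRIC_COLS]))))
  oc_row <- res$summary[res$summary$kind == "iforest", ]
  expect_true(is.na(oc_row$auc) && is.na(oc_row$eer))
  expect_true(all(oc_row[c("precision", "recall", "accuracy", "fpr")] >= 0))
  expect_equal(res$n_features, 672)
  # experiments are pure functions of (cohort, config, seed)
  res2 <- run_baseline(feats, list(fast_rf(), fast_if()), seed = 1)
  expect_identical(res$per_user, res2$per_user)
})

test_that("channel ablation yields one 48-feature row per channel", {
  feats <- test_cohort_features(2, 20, seed = 51)
  tab <- per_channel_experiment(feats, fast_rf(), seed = 2)
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$n_features == 48))
  expect_setequal(tab$channel, eegauth:::EEG_CHANNELS)
})

test_that("duplicated channels produce identical ablation rows", {
  set.seed(60)
  sig <- matrix(rnorm(2 * 2440), nrow = 2)
  cohort <- lapply(1:2, function(u) {
    s <- matrix(rnorm(2 * 2440), nrow = 2)
    s[2, ] <- s[1, ] # channel "B" is a copy of "A"
    eeg_recording(sprintf("user%02d", u), 256, c("A", "B"), s)
  })
  feats <- cohort_features(cohort)
  tab <- per_channel_experiment(feats, fast_rf(), seed = 3)
  a <- tab[tab$channel == "A", eegauth:::METRIC_COLS]
  b <- tab[tab$channel == "B", eegauth:::METRIC_COLS]
  expect_equal(unname(unlist(a)), unname(unlist(b)))
})

test_that("wave ablation yields one 112-feature row per band", {
  feats <- test_cohort_features(2, 20, seed = 51)
  tab <- per_wave_experiment(feats, fast_rf(), seed = 2)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$n_features == 112))
  expect_setequal(tab$wave, eegauth:::EEG_BANDS)
})

test_that("contamination sweep covers every kind/value pair on D1 features", {
  feats <- test_cohort_features(2, 20, seed = 51)
  tab <- contamination_sweep(feats,
    values = c(0.1, 0.5),
    oc_kinds = c("iforest", "lof"), seed = 4
  )
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$kind, c("iforest", "lof"))
  expect_true(all(is.na(tab$auc)))
  expect_error(contamination_sweep(feats, values = 0.7), "values")
})

test_that("the hybrid cascade consumes the configured feature subset", {
  feats <- test_cohort_features(3, 30, seed = 52)
  cfg <- hybrid_config("III",
    oc_spec = fast_if(), mc_spec = fast_rf(), seed = 5
  )
  res <- run_hybrid(feats, cfg)
  expect_equal(res$n_features, 112) # D1 x 14 channels x 8 metrics
  expect_equal(nrow(res$per_user), 3)
  expect_true(all(is.finite(res$per_user$accuracy)))
  expect_true(all(c("oc_accuracy", "oc_fpr") %in% names(res$summary)))

  cfg1 <- hybrid_config("I", oc_spec = fast_if(), mc_spec = fast_rf(), seed = 5)
  expect_equal(run_hybrid(feats, cfg1)$n_features, 40)
})

test_that("hybrid pools are disjoint and positives trace to their user", {
  feats <- test_cohort_features(3, 30, seed = 52)
  cfg <- hybrid_config("III", oc_spec = fast_if(), mc_spec = fast_rf(), seed = 6)
  res <- run_hybrid(feats, cfg)
  for (u in names(res$audit)) {
    a <- res$audit[[u]]
    ids <- c(a$oc_train, a$hybrid_train, a$final_test)
    expect_equal(anyDuplicated(ids), 0)
    expect_true(all(grepl(paste0("^", u), a$oc_train)))
  }
})

test_that("an oracle first layer reduces the cascade to supervised training", {
  feats <- test_cohort_features(3, 30, seed = 52)
  cfg <- hybrid_config("III", oc_spec = fast_if(), mc_spec = fast_rf(), seed = 7)
  res <- run_hybrid(feats, cfg, oracle_first_layer = TRUE)

  # rebuild the same pools from the audit trail and train the MC model
  # directly on ground truth: metrics must match exactly
  sub <- select_features(feats, waves = cfg$waves)
  all_ids <- paste(sub$row_meta$user_id, sub$row_meta$segment, sep = "::")
  for (u in unique(sub$row_meta$user_id)) {
    a <- res$audit[[u]]
    tr_rows <- match(a$hybrid_train, all_ids)
    te_rows <- match(a$final_test, all_ids)
    truth <- function(ids) as.integer(grepl(paste0("^", u, "::"), ids))
    sp <- structure(
      list(
        user_id = u, mode = "multi_class", seed = cfg$seed,
        train = list(
          x = sub$values[tr_rows, , drop = FALSE],
          y = truth(a$hybrid_train), ids = a$hybrid_train
        ),
        val = NULL,
        test = list(
          x = sub$values[te_rows, , drop = FALSE],
          y = truth(a$final_test), ids = a$final_test
        )
      ),
      class = "split_bundle"
    )
    direct <- evaluate_model(train_model(cfg$mc_spec, sp), sp)
    got <- unlist(res$per_user[res$per_user$user == u, eegauth:::METRIC_COLS])
    expect_equal(unname(got), unname(eegauth:::as_metric_row(direct)))
  }
})

test_that("permutation stability reports per-permutation rows plus mean and sd", {
  feats <- test_cohort_features(3, 30, seed = 52)
  cfg <- hybrid_config("III", oc_spec = fast_if(), mc_spec = fast_rf(), seed = 8)
  tab <- permutation_stability(feats, cfg, n_permutations = 3)
  expect_equal(tab$permutation, c("1", "2", "3", "mean", "sd"))
  expect_true(all(is.finite(tab$accuracy)))
  sd_row <- tab[tab$permutation == "sd", ]
  expect_true(all(sd_row[, c("accuracy", "precision", "recall")] >= 0))
})
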
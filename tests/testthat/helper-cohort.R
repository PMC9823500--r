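# Shared synthetic cohorts, memoised so several test files can reuse the
# same feature matrix without regenerating the signals.
.cohort_cache <- new.env(parent = emptyenv())

test_cohort_features <- function(n_users, duration_s, seed,
                                 identity_strength = 0.3,
                                 identity_bands = eegauth:::EEG_BANDS,
                                 within_user_jitter = 0.25) {
  key <- paste(n_users, duration_s, seed, identity_strength,
    paste(identity_bands, collapse = "+"), within_user_jitter,
    sep = "|"
  )
  if (is.null(.cohort_cache[[key]])) {
    cfg <- synthetic_config(
      n_users = n_users, duration_s = duration_s, seed = seed,
      identity_strength = identity_strength,
      identity_bands = identity_bands,
      within_user_jitter = within_user_jitter
    )
    .cohort_cache[[key]] <- cohort_features(generate_cohort(cfg))
  }
  .cohort_cache[[key]]
}

# A labelled feature_matrix of pure noise - enough structure for protocol
# and bookkeeping tests without any signal synthesis.
fake_features <- function(n_users = 3, segments_per_user = 30, p = 10,
                          seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(n_users * segments_per_user * p),
    ncol = p
  )
  index <- data.frame(
    channel = rep("AF3", p), band = rep("D1", p),
    metric = paste0("m", seq_len(p)), stringsAsFactors = FALSE
  )
  row_meta <- data.frame(
    user_id = rep(sprintf("user%02d", seq_len(n_users)),
      each = segments_per_user
    ),
    segment = rep(seq_len(segments_per_user), n_users),
    stringsAsFactors = FALSE
  )
  eegauth:::feature_matrix(values, index, row_meta)
}
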
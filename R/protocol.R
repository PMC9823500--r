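#' @section Enrollment/authentication protocol:
#' Every split is per target user: positives are the user's own segments,
#' negatives ("random forgeries") are segments of other users. Multi-class
#' splits are 50/50 positive/negative in every partition; one-class splits
#' train on positives only and test 50/50. The positive 80/20 split and the
#' negative draw use independent sub-seeds, so repeated runs can resample
#' impostors while keeping the positive partition fixed.
#' @name protocol
NULL

row_ids <- function(fm, rows) {
  paste(fm$row_meta$user_id[rows], fm$row_meta$segment[rows], sep = "::")
}

make_partition <- function(fm, rows, labels) {
  list(
    x = fm$values[rows, , drop = FALSE],
    y = as.integer(labels),
    ids = row_ids(fm, rows)
  )
}

check_split_pre <- function(target_user, cohort, min_segments = 10) {
  stopifnot(inherits(cohort, "feature_matrix"))
  n_pos <- sum(cohort$row_meta$user_id == target_user)
  if (n_pos == 0) stop("unknown user: ", target_user, call. = FALSE)
  if (n_pos < min_segments) {
    stop(
      "user ", target_user, " has only ", n_pos,
      " segments (need >= ", min_segments, ")",
      call. = FALSE
    )
  }
  if (!any(cohort$row_meta$user_id != target_user)) {
    stop("cohort needs at least one other user for negatives", call. = FALSE)
  }
}

draw_negatives <- function(cohort, target_user, n_needed, seed) {
  pool <- which(cohort$row_meta$user_id != target_user)
  if (length(pool) < n_needed) {
    stop(
      "not enough impostor segments: need ", n_needed, ", have ",
      length(pool),
      call. = FALSE
    )
  }
  with_seed(seed, sample(pool, n_needed))
}

#' Build the one-class enrollment/authentication split for one user
#'
#' Training uses 80% of the target user's segments (positives only); the
#' test set is the remaining 20% plus the same number of impostor segments
#' drawn uniformly without replacement from all other users.
#'
#' @param target_user user id whose authenticator is being built.
#' @param cohort cohort-wide `feature_matrix` (see [cohort_features()]).
#' @param seed integer seed driving the negative draw (and, by default, the
#'   positive split).
#' @param pos_seed seed for the positive 80/20 split; fix it across repeats
#'   to resample only negatives.
#' @return a `split_bundle` with `train` (positives only), `val` (`NULL`)
#'   and `test` partitions, each `list(x, y, ids)` with labels 1 =
#'   legitimate, 0 = impostor.
#' @export
make_oc_split <- function(target_user, cohort, seed, pos_seed = seed) {
  check_split_pre(target_user, cohort)
  pos <- which(cohort$row_meta$user_id == target_user)
  perm <- with_seed(derive_seed(pos_seed, "pos", target_user), sample(pos))
  n_train <- floor(0.8 * length(pos))
  train_pos <- perm[seq_len(n_train)]
  test_pos <- perm[-seq_len(n_train)]
  neg <- draw_negatives(
    cohort, target_user, length(test_pos),
    derive_seed(seed, "neg", target_user)
  )
  structure(
    list(
      user_id = target_user, mode = "one_class", seed = seed,
      train = make_partition(cohort, train_pos, rep(1, n_train)),
      val = NULL,
      test = make_partition(
        cohort, c(test_pos, neg),
        c(rep(1, length(test_pos)), rep(0, length(neg)))
      )
    ),
    class = "split_bundle"
  )
}

#' Build the multi-class (binary) split for one user
#'
#' Positives: 80% train / 20% test. Negatives: drawn uniformly without
#' replacement from all other users' segments and matched 1:1 per
#' partition. 15% of the combined train set is carved out as a validation
#' set, stratified by label.
#'
#' @inheritParams make_oc_split
#' @param val_fraction fraction of the combined train set held out for
#'   validation.
#' @return a `split_bundle` with balanced `train`, `val` and `test`
#'   partitions.
#' @export
make_mc_split <- function(target_user, cohort, seed, pos_seed = seed,
                          val_fraction = 0.15) {
  check_split_pre(target_user, cohort)
  pos <- which(cohort$row_meta$user_id == target_user)
  perm <- with_seed(derive_seed(pos_seed, "pos", target_user), sample(pos))
  n_train <- floor(0.8 * length(pos))
  train_pos <- perm[seq_len(n_train)]
  test_pos <- perm[-seq_len(n_train)]
  neg <- draw_negatives(
    cohort, target_user, n_train + length(test_pos),
    derive_seed(seed, "neg", target_user)
  )
  train_neg <- neg[seq_len(n_train)]
  test_neg <- neg[-seq_len(n_train)]

  # stratified validation carve-out from the combined train set
  n_val_per_class <- floor(val_fraction * n_train)
  val_pos_sel <- with_seed(
    derive_seed(seed, "val", target_user, "pos"),
    sample(seq_along(train_pos), n_val_per_class)
  )
  val_neg_sel <- with_seed(
    derive_seed(seed, "val", target_user, "neg"),
    sample(seq_along(train_neg), n_val_per_class)
  )
  val_rows <- c(train_pos[val_pos_sel], train_neg[val_neg_sel])
  val_y <- c(rep(1, n_val_per_class), rep(0, n_val_per_class))
  keep_pos <- if (n_val_per_class) train_pos[-val_pos_sel] else train_pos
  keep_neg <- if (n_val_per_class) train_neg[-val_neg_sel] else train_neg
  train_rows <- c(keep_pos, keep_neg)
  train_y <- c(rep(1, length(keep_pos)), rep(0, length(keep_neg)))

  structure(
    list(
      user_id = target_user, mode = "multi_class", seed = seed,
      train = make_partition(cohort, train_rows, train_y),
      val = make_partition(cohort, val_rows, val_y),
      test = make_partition(
        cohort, c(test_pos, test_neg),
        c(rep(1, length(test_pos)), rep(0, length(test_neg)))
      )
    ),
    class = "split_bundle"
  )
}

#' @export
print.split_bundle <- function(x, ...) {
  sizes <- vapply(
    Filter(Negate(is.null), x[c("train", "val", "test")]),
    function(p) length(p$y), integer(1)
  )
  cat(
    "<split_bundle>", x$mode, "for", x$user_id, "-",
    paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

#' Repeat a seeded experiment and summarize its metrics
#'
#' Runs `run(seed)` for `seeds base_seed .. base_seed + n_repeats - 1`
#' (fresh impostor draws each time when the closure forwards the seed to
#' the split makers) and returns the per-metric mean and standard
#' deviation.
#'
#' @param run function of one integer seed returning a named numeric vector
#'   of metrics.
#' @param n_repeats number of repetitions.
#' @param base_seed first seed.
#' @return list with `mean`, `sd` (named numeric) and `runs` (matrix, one
#'   row per repeat).
#' @export
repeat_experiment <- function(run, n_repeats = 3, base_seed = 1L) {
  stopifnot(n_repeats >= 1)
  runs <- lapply(seq_len(n_repeats) - 1L, function(k) {
    seed <- base_seed + k
    res <- tryCatch(run(seed), error = function(e) {
      stop("repeat with seed ", seed, " failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    res
  })
  runs <- do.call(rbind, runs)
  sds <- apply(runs, 2, sd)
  sds[is.na(sds)] <- 0
  list(mean = colMeans(runs), sd = sds, runs = runs)
}
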
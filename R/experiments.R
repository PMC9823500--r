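METRIC_COLS <- c("precision", "recall", "f1", "accuracy", "fpr", "auc", "eer")

as_metric_row <- function(m) {
  out <- rep(NA_real_, length(METRIC_COLS))
  names(out) <- METRIC_COLS
  out[intersect(names(m), METRIC_COLS)] <- m[intersect(names(m), METRIC_COLS)]
  out
}

run_one_user <- function(spec, cohort, user, seed, reduction = NULL) {
  split <- if (spec$kind %in% OC_KINDS) {
    make_oc_split(user, cohort, seed)
  } else {
    make_mc_split(user, cohort, seed)
  }
  if (!is.null(reduction)) {
    split <- reduce_split(split, reduction$method, reduction$k)
  }
  model <- train_model(spec, split)
  evaluate_model(model, split)
}

#' Baseline per-user authentication runs, macro-averaged over the cohort
#'
#' Trains and evaluates each classifier spec for every user under the
#' enrollment/authentication protocol and macro-averages the metrics over
#' users (AUC and EER only for the score-producing multi-class kinds).
#'
#' @param cohort cohort-wide `feature_matrix`.
#' @param specs list of [classifier_spec()] objects (a single spec is
#'   accepted).
#' @param seed integer seed driving all splits.
#' @param reduction optional `list(method = "pca"|"chi2", k = <int>)`
#'   applied per split, fitted on train rows only.
#' @return list with `per_user` (data.frame: user, kind, metrics),
#'   `summary` (one row per kind, macro-averaged) and `n_features`.
#' @export
run_baseline <- function(cohort, specs, seed = 1L, reduction = NULL) {
  stopifnot(inherits(cohort, "feature_matrix"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  users <- unique(cohort$row_meta$user_id)
  if (length(users) < 2) stop("need at least 2 users", call. = FALSE)
  per_user <- do.call(rbind, lapply(specs, function(spec) {
    rows <- lapply(users, function(u) {
      m <- tryCatch(
        run_one_user(spec, cohort, u, seed, reduction),
        error = function(e) {
          stop("user ", u, " (", spec$kind, "): ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      data.frame(
        user = u, kind = spec$kind, t(as_metric_row(m)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }))
  summary <- stats::aggregate(
    per_user[METRIC_COLS],
    by = list(kind = per_user$kind), FUN = mean
  )
  summary <- summary[match(
    unique(vapply(specs, `[[`, "", "kind")),
    summary$kind
  ), , drop = FALSE]
  rownames(summary) <- NULL
  list(
    per_user = per_user, summary = summary,
    n_features = ncol(cohort$values)
  )
}

#' Single-channel ablation: authenticate from 48 features at a time
#'
#' Reruns the baseline on each channel's 6 x 8 = 48 feature block and
#' tabulates the cohort-averaged metrics per channel.
#'
#' @inheritParams run_baseline
#' @return data.frame: one row per (channel, kind) with `n_features` and
#'   the macro-averaged metrics.
#' @export
per_channel_experiment <- function(cohort, specs, seed = 1L) {
  channels <- unique(cohort$index$channel)
  do.call(rbind, lapply(channels, function(ch) {
    sub <- select_features(cohort, channels = ch)
    res <- run_baseline(sub, specs, seed)
    cbind(
      channel = ch, n_features = res$n_features, res$summary,
      stringsAsFactors = FALSE
    )
  }))
}

#' Single-brainwave ablation: authenticate from 112 features at a time
#'
#' As [per_channel_experiment()], but per wavelet band (14 channels x 8
#' metrics = 112 features each on the full montage).
#'
#' @inheritParams run_baseline
#' @return data.frame: one row per (band, kind).
#' @export
per_wave_experiment <- function(cohort, specs, seed = 1L) {
  waves <- unique(cohort$index$band)
  do.call(rbind, lapply(waves, function(b) {
    sub <- select_features(cohort, waves = b)
    res <- run_baseline(sub, specs, seed)
    cbind(
      wave = b, n_features = res$n_features, res$summary,
      stringsAsFactors = FALSE
    )
  }))
}

#' Sweep the nu / contamination security-usability dial
#'
#' Evaluates each one-class kind at every value of its rejection-budget
#' parameter (nu for the one-class SVM, contamination for isolation forest
#' and LOF) on the gamma-band (D1) feature subset, cohort-averaged. Low
#' values accept almost everything (usable, insecure); high values reject
#' aggressively (secure, unusable).
#'
#' @param cohort cohort-wide `feature_matrix`.
#' @param values parameter values in (0, 0.5].
#' @param oc_kinds subset of `c("oc_svm", "iforest", "lof")`.
#' @param seed integer seed.
#' @param waves band subset to authenticate from (default D1).
#' @return data.frame: one row per (kind, value) with macro-averaged
#'   metrics.
#' @export
contamination_sweep <- function(cohort,
                                values = c(0.01, 0.03, 0.05, 0.1, 0.3, 0.5),
                                oc_kinds = c("oc_svm", "iforest", "lof"),
                                seed = 1L, waves = "D1") {
  stopifnot(all(values > 0 & values <= 0.5))
  sub <- select_features(cohort, waves = waves)
  do.call(rbind, lapply(oc_kinds, function(kind) {
    do.call(rbind, lapply(values, function(v) {
      spec <- if (kind == "oc_svm") {
        classifier_spec("oc_svm", nu = v)
      } else if (kind == "iforest") {
        classifier_spec("iforest", contamination = v)
      } else {
        classifier_spec("lof", contamination = v)
      }
      res <- run_baseline(sub, spec, seed)
      cbind(value = v, res$summary, stringsAsFactors = FALSE)
    }))
  }))
}

#' Configuration of the hybrid one-class to multi-class cascade
#'
#' Named presets follow the studied configurations: `"I"` (D1, channels
#' AF3/P8/T8/FC6/F4), `"II"` (D1, those plus O1/O2), `"III"` (D1, all
#' channels), `"IV"` (D1+D2, the five channels of I), `"V"` (D1+D2+D3,
#' same channels), `"complete"` (everything). The first layer defaults to
#' an isolation forest with contamination 0.3; the second to a random
#' forest.
#'
#' @param name preset label, or `"custom"` with explicit `waves`/`channels`.
#' @param waves,channels feature subset (`NULL` = all).
#' @param oc_spec,mc_spec first- and second-layer [classifier_spec()]s.
#' @param split_fractions positive fractions `(oc_train, hybrid_train,
#'   final_test)` over the user's positives, summing to 1.
#' @param seed integer seed.
#' @return an object of class `hybrid_config`.
#' @export
hybrid_config <- function(name = "III", waves = NULL, channels = NULL,
                          oc_spec = classifier_spec("iforest", contamination = 0.3),
                          mc_spec = classifier_spec("rf"),
                          split_fractions = c(0.6, 0.2, 0.2),
                          seed = 1L) {
  five <- c("AF3", "P8", "T8", "FC6", "F4")
  presets <- list(
    I = list(waves = "D1", channels = five),
    II = list(waves = "D1", channels = c("AF3", "O1", "O2", "P8", "T8", "FC6", "F4")),
    III = list(waves = "D1", channels = NULL),
    IV = list(waves = c("D1", "D2"), channels = five),
    V = list(waves = c("D1", "D2", "D3"), channels = five),
    complete = list(waves = NULL, channels = NULL)
  )
  if (name %in% names(presets)) {
    waves <- presets[[name]]$waves
    channels <- presets[[name]]$channels
  }
  if (length(split_fractions) != 3 || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split_fractions must be 3 positive numbers summing to 1",
      call. = FALSE
    )
  }
  structure(
    list(
      name = name, waves = waves, channels = channels, oc_spec = oc_spec,
      mc_spec = mc_spec, split_fractions = split_fractions,
      seed = as.integer(seed)
    ),
    class = "hybrid_config"
  )
}

#' Run the hybrid one-class to multi-class cascade
#'
#' Per user: (1) the one-class model is trained on the `oc_train` fraction
#' of the user's positives; (2) a disjoint hybrid-train pool (held-out
#' positives plus matched impostors) is labeled *by the one-class model*;
#' (3) the multi-class model is trained on those assigned labels; (4) it
#' is evaluated against ground truth on a disjoint final-test pool with a
#' fresh impostor draw. Only legitimate-user ground truth is ever needed
#' by the deployed system. For reference, the one-class layer alone is
#' also evaluated on the same final-test pool (`oc_*` columns).
#'
#' @param cohort cohort-wide `feature_matrix`.
#' @param config a [hybrid_config()].
#' @param oracle_first_layer if `TRUE`, the one-class labels on the hybrid
#'   pool are replaced by ground truth, reducing the cascade to ordinary
#'   supervised training (a debugging/upper-bound mode).
#' @return list with `per_user`, macro-averaged `summary` (one row; hybrid
#'   metrics plus `oc_accuracy` etc.), `n_features`, and a per-user
#'   `audit` of the disjoint row-id pools.
#' @export
run_hybrid <- function(cohort, config, oracle_first_layer = FALSE) {
  stopifnot(inherits(cohort, "feature_matrix"), inherits(config, "hybrid_config"))
  sub <- select_features(cohort, waves = config$waves, channels = config$channels)
  users <- unique(sub$row_meta$user_id)
  audit <- list()
  per_user <- do.call(rbind, lapply(users, function(u) {
    pos <- which(sub$row_meta$user_id == u)
    n <- length(pos)
    if (n < 15) stop("user ", u, " has too few segments for the three-way split", call. = FALSE)
    perm <- with_seed(derive_seed(config$seed, "pos", u), sample(pos))
    n1 <- floor(config$split_fractions[1] * n)
    n2 <- floor(config$split_fractions[2] * n)
    oc_rows <- perm[seq_len(n1)]
    hyb_pos <- perm[n1 + seq_len(n2)]
    fin_pos <- perm[(n1 + n2 + 1):n]
    neg <- draw_negatives(
      sub, u, n2 + length(fin_pos),
      derive_seed(config$seed, "neg", u)
    )
    hyb_neg <- neg[seq_len(n2)]
    fin_neg <- neg[-seq_len(n2)]

    oc_split <- structure(
      list(
        user_id = u, mode = "one_class", seed = config$seed,
        train = make_partition(sub, oc_rows, rep(1, n1)),
        val = NULL,
        test = make_partition(
          sub, c(fin_pos, fin_neg),
          c(rep(1, length(fin_pos)), rep(0, length(fin_neg)))
        )
      ),
      class = "split_bundle"
    )
    t0 <- proc.time()[["elapsed"]]
    oc_model <- train_model(config$oc_spec, oc_split)
    oc_time <- proc.time()[["elapsed"]] - t0

    hyb_rows <- c(hyb_pos, hyb_neg)
    hyb_truth <- c(rep(1L, length(hyb_pos)), rep(0L, length(hyb_neg)))
    hyb_x <- sub$values[hyb_rows, , drop = FALSE]
    oc_labels <- if (oracle_first_layer) {
      hyb_truth
    } else {
      predict(oc_model, hyb_x)
    }
    mc_split <- structure(
      list(
        user_id = u, mode = "multi_class", seed = config$seed,
        train = list(x = hyb_x, y = oc_labels, ids = row_ids(sub, hyb_rows)),
        val = NULL,
        test = oc_split$test
      ),
      class = "split_bundle"
    )
    t0 <- proc.time()[["elapsed"]]
    mc_model <- train_model(config$mc_spec, mc_split)
    mc_time <- proc.time()[["elapsed"]] - t0

    hybrid <- evaluate_model(mc_model, mc_split)
    oc_alone <- classification_metrics(confusion_counts(
      oc_split$test$y, predict(oc_model, oc_split$test$x)
    ))
    audit[[u]] <<- list(
      oc_train = row_ids(sub, oc_rows),
      hybrid_train = row_ids(sub, hyb_rows),
      final_test = oc_split$test$ids
    )
    data.frame(
      user = u, t(as_metric_row(hybrid)),
      oc_precision = oc_alone[["precision"]], oc_recall = oc_alone[["recall"]],
      oc_f1 = oc_alone[["f1"]], oc_accuracy = oc_alone[["accuracy"]],
      oc_fpr = oc_alone[["fpr"]],
      oc_train_time_s = oc_time, mc_train_time_s = mc_time,
      stringsAsFactors = FALSE
    )
  }))
  num_cols <- setdiff(names(per_user), "user")
  summary <- as.data.frame(t(colMeans(per_user[num_cols])))
  list(
    per_user = per_user, summary = summary,
    n_features = ncol(sub$values), config = config, audit = audit
  )
}

#' Re-run the hybrid system under segment-order permutations
#'
#' Randomly permutes every user's segment order `n_permutations` times
#' (seeded), re-runs [run_hybrid()] on each permuted cohort, and reports
#' the per-metric mean and standard deviation - a stability check that the
#' split randomization, not the user identity, is what varies.
#'
#' @inheritParams run_hybrid
#' @param n_permutations number of permutations.
#' @return data.frame with one row per permutation plus `mean` and `sd`
#'   rows.
#' @export
permutation_stability <- function(cohort, config, n_permutations = 5) {
  users <- unique(cohort$row_meta$user_id)
  rows <- lapply(seq_len(n_permutations), function(p) {
    ord <- unlist(lapply(users, function(u) {
      idx <- which(cohort$row_meta$user_id == u)
      with_seed(derive_seed(config$seed, "permutation", p, u), sample(idx))
    }))
    permuted <- subset_rows(cohort, ord)
    res <- run_hybrid(permuted, config)
    cbind(permutation = as.character(p), res$summary, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num_cols <- setdiff(names(tab), "permutation")
  mean_row <- cbind(
    permutation = "mean", as.data.frame(t(colMeans(tab[num_cols]))),
    stringsAsFactors = FALSE
  )
  sds <- apply(tab[num_cols], 2, sd)
  sds[is.na(sds)] <- 0
  sd_row <- cbind(
    permutation = "sd", as.data.frame(t(sds)),
    stringsAsFactors = FALSE
  )
  rbind(tab, mean_row, sd_row)
}
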
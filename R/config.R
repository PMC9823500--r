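#' Default run configuration
#'
#' Returns the fully materialized defaults for every section: the synthetic
#' cohort (39 users, 14 channels, 256 Hz, 120 s), the feature extractor
#' (240 ms windows, db2, 5 levels), the protocol (3 repeats, 15%
#' validation), per-model overrides, the optional reduction, and the
#' experiment selection. [load_config()] merges a user file over this
#' structure.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(
    list(
      seed = 1L,
      output_dir = "runs",
      synth = list(
        n_users = 39L, n_channels = 14L, channel_names = EEG_CHANNELS,
        fs = 256, duration_s = 120, identity_strength = 0.3,
        within_user_jitter = 0.25, identity_bands = EEG_BANDS,
        background_level = 0.6
      ),
      features = list(window_ms = 240, wavelet = "db2", levels = 5L),
      protocol = list(n_repeats = 3L, val_fraction = 0.15),
      models = list(
        svm = list(cv_folds = 10L),
        rf = list(n_estimators = 500L),
        knn = list(k_neighbors = 25L),
        oc_svm = list(nu = 0.5),
        iforest = list(n_estimators = 500L, contamination = 0.3),
        lof = list(k_neighbors = 25L, contamination = 0.3)
      ),
      reduction = list(method = NULL, k = NULL),
      experiment = list(
        name = "baseline",
        kinds = c("rf", "iforest"),
        hybrid = "III"
      )
    ),
    class = "run_config"
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.null(user[[key]])) next # a null entry means "keep the default"
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  check <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  s <- cfg$synth
  check(s$fs > 0, "synth.fs must be positive")
  check(s$duration_s > 0, "synth.duration_s must be positive")
  check(s$n_channels == length(s$channel_names),
    "synth.n_channels must equal length(synth.channel_names)")
  check(all(s$identity_bands %in% EEG_BANDS) && length(s$identity_bands) > 0,
    "synth.identity_bands must be a non-empty subset of the six band labels")
  check(s$identity_strength >= 0 && s$within_user_jitter >= 0 &&
    s$background_level >= 0,
  "synth noise scales must be >= 0")
  check(cfg$features$window_ms > 0, "features.window_ms must be positive")
  check(cfg$features$levels >= 1, "features.levels must be >= 1")
  check(cfg$protocol$n_repeats >= 1, "protocol.n_repeats must be >= 1")
  check(cfg$protocol$val_fraction >= 0 && cfg$protocol$val_fraction < 1,
    "protocol.val_fraction must be in [0, 1)")
  for (kind in c("iforest", "lof")) {
    v <- cfg$models[[kind]]$contamination
    check(is.null(v) || (v > 0 && v <= 0.5),
      paste0("models.", kind, ".contamination must be in (0, 0.5]"))
  }
  v <- cfg$models$oc_svm$nu
  check(is.null(v) || (v > 0 && v <= 1), "models.oc_svm.nu must be in (0, 1]")
  if (!is.null(cfg$reduction$method)) {
    check(cfg$reduction$method %in% c("pca", "chi2"),
      "reduction.method must be 'pca' or 'chi2'")
    check(!is.null(cfg$reduction$k) && cfg$reduction$k >= 1,
      "reduction.k must be a positive count")
  }
  check(all(cfg$experiment$kinds %in% c(MC_KINDS, OC_KINDS)),
    "experiment.kinds must name known classifier kinds")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads YAML (or JSON), merges it over [default_run_config()] - so an
#' empty file yields all defaults - rejects unknown keys, and validates
#' bounds, naming the offending key.
#'
#' @param path YAML or JSON file.
#' @return a validated `run_config` with all defaults materialized.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(default_run_config(), user %||% list())
  validate_config(structure(cfg, class = "run_config"))
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Display-name mapping used for the human-readable result tables.
RESULT_HEADERS <- c(
  auc = "AUC", eer = "EER", precision = "Prec.", recall = "Recall",
  f1 = "F1", accuracy = "Acc", fpr = "FPR"
)

#' Column schema for a result table
#'
#' Multi-class tables carry AUC and EER; one-class tables do not, since
#' those models emit hard accept/reject decisions rather than scores.
#'
#' @param kind `"mc"` or `"oc"`.
#' @param id_cols leading identifier columns (e.g. `"kind"`, `"channel"`).
#' @return character vector of column names in order.
#' @export
result_schema <- function(kind = c("mc", "oc"), id_cols = "kind") {
  kind <- match.arg(kind)
  metrics <- if (kind == "mc") {
    c("auc", "eer", "precision", "recall", "f1", "accuracy", "fpr")
  } else {
    c("precision", "recall", "f1", "accuracy", "fpr")
  }
  c(id_cols, metrics)
}

#' Write a result table as a human CSV plus a full-precision JSON sibling
#'
#' The CSV uses the conventional headers (AUC, EER, Prec., Recall, F1,
#' Acc, FPR) with floats at 3 decimals; the JSON sibling (same path with
#' `.json`) keeps full precision and the internal column names.
#'
#' @param table data.frame of results.
#' @param schema character vector of required columns in order (see
#'   [result_schema()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(table, schema, path) {
  missing <- setdiff(schema, names(table))
  if (length(missing)) {
    stop("table is missing schema column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  table <- table[, schema, drop = FALSE]
  jsonlite::write_json(
    table, sub("\\.csv$", ".json", path),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  human <- table
  for (j in seq_along(human)) {
    if (is.numeric(human[[j]])) human[[j]] <- round(human[[j]], 3)
  }
  names(human) <- ifelse(
    names(human) %in% names(RESULT_HEADERS),
    RESULT_HEADERS[names(human)], names(human)
  )
  write.csv(human, path, row.names = FALSE)
  invisible(path)
}
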
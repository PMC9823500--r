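# Metric names in feature-column order.
FEATURE_METRICS <- c(
  "max", "min", "mean", "std", "var", "skewness", "shannon_entropy",
  "avg_power"
)

#' Cut a recording into consecutive non-overlapping analysis windows
#'
#' Window length is `floor(window_ms * fs / 1000)` samples (61 at 256 Hz for
#' the default 240 ms); the trailing partial window is discarded. Each
#' window is one authentication sample.
#'
#' @param recording an [eeg_recording()].
#' @param window_ms window length in milliseconds.
#' @return an object of class `segment_array`: list with `user_id`, `fs`,
#'   `channel_names`, `window_samples` and `segments`, a numeric array
#'   `[n_segments, n_channels, window_samples]`.
#' @export
segment_signal <- function(recording, window_ms = 240) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  w <- floor(window_ms * recording$fs / 1000)
  if (w < 1) stop("window shorter than one sample", call. = FALSE)
  n <- ncol(recording$signal)
  m <- n %/% w
  nch <- nrow(recording$signal)
  segs <- array(0, dim = c(m, nch, w))
  if (m > 0) {
    for (j in seq_len(m)) {
      segs[j, , ] <- recording$signal[, ((j - 1) * w + 1):(j * w), drop = FALSE]
    }
  }
  structure(
    list(
      user_id = recording$user_id, fs = recording$fs,
      channel_names = recording$channel_names, window_samples = w,
      segments = segs
    ),
    class = "segment_array"
  )
}

#' Eight summary statistics of a wavelet coefficient vector
#'
#' In column order: maximum, minimum, mean, standard deviation, variance,
#' skewness, Shannon entropy and average power. Standard deviation,
#' variance and skewness use population normalization (divide by n);
#' skewness is 0 for a zero-variance vector. Shannon entropy is computed on
#' the normalized coefficient-energy distribution `p_k = x_k^2 / sum x_j^2`
#' in bits (`-sum p_k log2 p_k`, with `0 log 0 := 0`), and is 0 when the
#' total energy is 0. Average power is `mean(x^2)`.
#'
#' @param coeffs non-empty finite numeric vector.
#' @return named numeric vector of length 8.
#' @export
#' @examples
#' coefficient_metrics(c(5, 0, 0, 0))
coefficient_metrics <- function(coeffs) {
  if (length(coeffs) == 0) stop("coeffs must be non-empty", call. = FALSE)
  if (!all(is.finite(coeffs))) stop("coeffs must be finite", call. = FALSE)
  drop(metrics_block(matrix(coeffs, ncol = 1)))
}

# Vectorized metrics: M is coefficients x m; returns 8 x m with rownames
# FEATURE_METRICS.
metrics_block <- function(M) {
  m <- ncol(M)
  n <- nrow(M)
  mu <- colMeans(M)
  p2 <- colMeans(M^2)
  v <- pmax(p2 - mu^2, 0) # population variance
  s <- sqrt(v)
  centered <- sweep(M, 2, mu)
  m3 <- colMeans(centered^3)
  skew <- ifelse(s > 0, m3 / s^3, 0)
  energy <- M^2
  tot <- colSums(energy)
  ent <- numeric(m)
  pos <- tot > 0
  if (any(pos)) {
    p <- sweep(energy[, pos, drop = FALSE], 2, tot[pos], "/")
    plogp <- p * log2(p)
    plogp[p == 0] <- 0
    ent[pos] <- -colSums(plogp)
  }
  mx <- do.call(pmax, lapply(seq_len(n), function(i) M[i, ]))
  mn <- do.call(pmin, lapply(seq_len(n), function(i) M[i, ]))
  out <- rbind(mx, mn, mu, s, v, skew, ent, p2)
  rownames(out) <- FEATURE_METRICS
  out
}

# Constructor for the segments x features container used everywhere
# downstream.
feature_matrix <- function(values, index, row_meta) {
  stopifnot(ncol(values) == nrow(index), nrow(values) == nrow(row_meta))
  colnames(values) <- paste(index$channel, index$band, index$metric, sep = "__")
  structure(
    list(values = values, index = index, row_meta = row_meta),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(
    "<feature_matrix>", nrow(x$values), "segments x", ncol(x$values),
    "features (", length(unique(x$index$channel)), "channels x",
    length(unique(x$index$band)), "bands x 8 metrics ),",
    length(unique(x$row_meta$user_id)), "user(s)\n"
  )
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Extract wavelet-statistics features from segmented EEG
#'
#' For every segment and channel, runs the five-level db2 decomposition and
#' computes the eight statistics of each of the six coefficient vectors.
#' Columns are ordered channel-major, then band (D1, D2, D3, D4, D5, A5),
#' then metric, giving `n_channels * 6 * 8` features (672 for 14 channels).
#'
#' @param segments a [segment_signal()] result with at least one segment.
#' @param fs sampling rate in Hz (defaults to the recording's).
#' @return a `feature_matrix`: `values` (segments x features), `index`
#'   (channel/band/metric per column) and `row_meta` (user_id, segment).
#' @export
build_feature_matrix <- function(segments, fs = segments$fs) {
  stopifnot(inherits(segments, "segment_array"))
  m <- dim(segments$segments)[1]
  if (m < 1) stop("no segments to featurize", call. = FALSE)
  nch <- length(segments$channel_names)
  w <- segments$window_samples
  blocks <- vector("list", nch)
  for (ci in seq_len(nch)) {
    X <- t(array(segments$segments[, ci, , drop = FALSE], dim = c(m, w)))
    bands <- tryCatch(
      dwt_bands_matrix(X),
      error = function(e) {
        stop(
          "decomposition failed for channel ", segments$channel_names[ci],
          ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    blocks[[ci]] <- do.call(rbind, lapply(EEG_BANDS, function(b) {
      metrics_block(bands[[b]])
    }))
  }
  values <- t(do.call(rbind, blocks))
  index <- data.frame(
    channel = rep(segments$channel_names, each = 6 * 8),
    band = rep(rep(EEG_BANDS, each = 8), times = nch),
    metric = rep(FEATURE_METRICS, times = 6 * nch),
    stringsAsFactors = FALSE
  )
  row_meta <- data.frame(
    user_id = rep(segments$user_id, m), segment = seq_len(m),
    stringsAsFactors = FALSE
  )
  feature_matrix(values, index, row_meta)
}

#' Extract features for a whole cohort
#'
#' Convenience wrapper: segments every recording and stacks the per-user
#' feature matrices row-wise.
#'
#' @param cohort list of [eeg_recording()] objects.
#' @param window_ms analysis window in milliseconds.
#' @return a `feature_matrix` whose `row_meta$user_id` identifies the owner
#'   of every row.
#' @export
cohort_features <- function(cohort, window_ms = 240) {
  fms <- lapply(cohort, function(rec) {
    build_feature_matrix(segment_signal(rec, window_ms))
  })
  rbind_features(fms)
}

# Stack feature matrices with identical indices.
rbind_features <- function(fms) {
  stopifnot(length(fms) >= 1)
  idx <- fms[[1]]$index
  for (fm in fms[-1]) {
    if (!identical(fm$index, idx)) {
      stop("feature matrices have different indices", call. = FALSE)
    }
  }
  feature_matrix(
    do.call(rbind, lapply(fms, function(f) f$values)),
    idx,
    do.call(rbind, lapply(fms, function(f) f$row_meta))
  )
}

# Row subset preserving metadata.
subset_rows <- function(fm, rows) {
  feature_matrix(
    fm$values[rows, , drop = FALSE], fm$index,
    fm$row_meta[rows, , drop = FALSE]
  )
}

#' Select feature columns by brainwave band and/or channel
#'
#' Restricts a feature matrix to the requested channels and bands, keeping
#' the original channel-major column order. One channel keeps 6 x 8 = 48
#' features; one band keeps `n_channels` x 8 (112 for 14 channels).
#'
#' @param fm a `feature_matrix`.
#' @param waves band labels to keep (default all present).
#' @param channels channel labels to keep (default all present).
#' @return the filtered `feature_matrix`.
#' @export
select_features <- function(fm, waves = NULL, channels = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  all_waves <- unique(fm$index$band)
  all_channels <- unique(fm$index$channel)
  waves <- waves %||% all_waves
  channels <- channels %||% all_channels
  unknown <- c(setdiff(waves, all_waves), setdiff(channels, all_channels))
  if (length(unknown)) {
    stop("unknown channel/band label(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- fm$index$band %in% waves & fm$index$channel %in% channels
  feature_matrix(
    fm$values[, keep, drop = FALSE],
    fm$index[keep, , drop = FALSE],
    fm$row_meta
  )
}

#' Standard (z-score) normalization fitted on the training rows only
#'
#' Per feature, subtracts the train mean and divides by the train standard
#' deviation; features constant in train map to 0 everywhere. The same
#' train-fitted transform is applied to every other matrix, so no test
#' information leaks into the scaling.
#'
#' @param train numeric matrix (or `feature_matrix`) with >= 2 rows.
#' @param others list of matrices with the same columns.
#' @return list with `train`, `others` (transformed), and the fitted
#'   per-feature `center` and `scale`.
#' @export
standardize_features <- function(train, others = list()) {
  tx <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  if (nrow(tx) < 2) stop("train must have >= 2 rows", call. = FALSE)
  center <- colMeans(tx)
  scale <- apply(tx, 2, sd)
  apply_std <- function(x) {
    x <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
    out <- sweep(x, 2, center)
    out <- sweep(out, 2, ifelse(scale > 0, scale, 1), "/")
    out[, scale == 0] <- 0
    out
  }
  list(
    train = apply_std(tx), others = lapply(others, apply_std),
    center = center, scale = scale
  )
}

#' Write a feature matrix to CSV
#'
#' Header: `user_id`, `segment`, then one `<channel>__<band>__<metric>`
#' token per feature. [read_feature_csv()] restores an identical
#' `feature_matrix`.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_feature_csv <- function(fm, path) {
  df <- cbind(fm$row_meta, as.data.frame(fm$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- c("user_id", "segment")
  feat_cols <- setdiff(names(df), meta_cols)
  parts <- strsplit(feat_cols, "__", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("malformed feature column header", call. = FALSE)
  }
  index <- data.frame(
    channel = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    metric = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE
  )
  feature_matrix(
    as.matrix(df[, feat_cols, drop = FALSE]), index,
    df[, meta_cols, drop = FALSE]
  )
}
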
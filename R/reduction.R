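#' Principal-component projection fitted on training rows only
#'
#' Projects onto the top-`k` variance-ordered orthonormal components of the
#' centered train matrix and applies the same train-fitted projection to
#' every other matrix. Component signs are fixed so that each component's
#' largest-magnitude loading is positive (pure reporting determinism).
#'
#' @param train numeric matrix (or `feature_matrix`) of training rows.
#' @param others list of matrices with the same columns.
#' @param k number of components; `k <= min(nrow(train) - 1, ncol(train))`.
#' @return list with projected `train`, `others`, the
#'   `explained_variance` fraction of the kept components, `rotation` and
#'   the train `center`.
#' @export
pca_reduce <- function(train, others = list(), k) {
  x <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  if (k > min(nrow(x) - 1, ncol(x))) {
    stop("k must be <= min(n_train_rows - 1, n_features)", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  rot <- sweep(rot, 2, flip, "*")
  tot <- sum(pc$sdev^2)
  project <- function(m) {
    m <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
    out <- sweep(m, 2, pc$center) %*% rot
    colnames(out) <- paste0("PC", seq_len(k))
    out
  }
  list(
    train = project(x), others = lapply(others, project),
    explained_variance = if (tot > 0) sum(pc$sdev[seq_len(k)]^2) / tot else 1,
    rotation = rot, center = pc$center
  )
}

# Chi-squared feature-selection statistic: features are first min-max
# scaled to [0, 1] on the train rows (the statistic requires non-negative
# mass); the observed per-class feature sums are compared with the
# allocation expected from the class frequencies.
chi2_statistics <- function(x, y) {
  rng_min <- apply(x, 2, min)
  rng_max <- apply(x, 2, max)
  span <- rng_max - rng_min
  xs <- sweep(x, 2, rng_min)
  xs <- sweep(xs, 2, ifelse(span > 0, span, 1), "/")
  xs[, span == 0] <- 0
  classes <- sort(unique(y))
  n <- length(y)
  tot <- colSums(xs)
  stat <- numeric(ncol(x))
  for (cls in classes) {
    rows <- y == cls
    observed <- colSums(xs[rows, , drop = FALSE])
    expected <- tot * sum(rows) / n
    ok <- expected > 0
    stat[ok] <- stat[ok] + (observed[ok] - expected[ok])^2 / expected[ok]
  }
  stat
}

#' Chi-squared univariate feature selection fitted on training rows only
#'
#' Ranks features by the class-association chi-squared statistic computed
#' on min-max-scaled train columns and keeps the top `k`; the same column
#' subset is applied to every other matrix. Ties break toward the original
#' column order.
#'
#' @param train numeric matrix of training rows.
#' @param train_labels binary labels for `train`; both classes must be
#'   present.
#' @param others list of matrices with the same columns.
#' @param k number of features to keep.
#' @return list with column-subset `train` and `others`, the kept column
#'   indices `selected`, and the per-feature `statistics`.
#' @export
chi2_select <- function(train, train_labels, others = list(), k) {
  x <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  y <- as.integer(train_labels)
  if (k > ncol(x)) stop("k must be <= n_features", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("chi-squared selection needs two classes", call. = FALSE)
  }
  stat <- chi2_statistics(x, y)
  selected <- order(-stat)[seq_len(k)] # order() is stable: ties keep column order
  selected <- sort(selected) # preserve original column order in the output
  take <- function(m) {
    m <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
    m[, selected, drop = FALSE]
  }
  list(
    train = take(x), others = lapply(others, take),
    selected = selected, statistics = stat
  )
}

#' Apply a reduction spec to a split bundle
#'
#' Fits the reduction on the split's train partition only and transforms
#' train, validation and test consistently.
#'
#' @param split a `split_bundle`.
#' @param method `"pca"` or `"chi2"`.
#' @param k target dimensionality.
#' @return the transformed `split_bundle` (an attribute `reduction` holds
#'   fit details).
#' @export
reduce_split <- function(split, method = c("pca", "chi2"), k) {
  method <- match.arg(method)
  parts <- Filter(Negate(is.null), split[c("val", "test")])
  others <- lapply(parts, function(p) p$x)
  red <- if (method == "pca") {
    pca_reduce(split$train$x, others, k)
  } else {
    chi2_select(split$train$x, split$train$y, others, k)
  }
  split$train$x <- red$train
  for (nm in names(parts)) split[[nm]]$x <- red$others[[nm]]
  attr(split, "reduction") <- red[setdiff(
    names(red),
    c("train", "others")
  )]
  split
}
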
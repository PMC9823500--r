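#' Local outlier factor in novelty mode
#'
#' Fits the reference density on training points only (Breunig et al.'s
#' reachability-based local density), then scores unseen points against
#' that reference: a score much greater than 1 means the point sits in a
#' sparser region than its k nearest training neighbours. Novelty mode is
#' what a verification protocol needs - test segments are never part of
#' the neighbourhood structure they are judged against.
#'
#' @param x numeric training matrix.
#' @param k number of neighbours.
#' @return an object of class `lof_model`.
#' @export
lof_fit <- function(x, k = 25) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("LOF needs at least 2 training rows", call. = FALSE)
  k <- min(k, n - 1)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) d[i, nn[i, k]], 0)
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nn[i, ]], d[i, nn[i, ]])
    m <- mean(reach)
    if (m == 0) Inf else 1 / m
  }, 0)
  structure(
    list(x = x, k = k, kdist = kdist, lrd = lrd),
    class = "lof_model"
  )
}

# Train-side LOF of each training point (used for contamination
# thresholding).
lof_train_scores <- function(fit) {
  n <- nrow(fit$x)
  d <- as.matrix(dist(fit$x))
  diag(d) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(fit$k)]
    reach <- pmax(fit$kdist[nb], d[i, nb])
    m <- mean(reach)
    lrd_i <- if (m == 0) Inf else 1 / m
    r <- mean(fit$lrd[nb]) / lrd_i
    if (is.nan(r)) 1 else r
  }, 0)
}

#' @rdname lof_fit
#' @param fit a `lof_model`.
#' @return `lof_score`: LOF scores of the rows of `x` relative to the
#'   training set (higher = more anomalous).
#' @export
lof_score <- function(fit, x) {
  stopifnot(inherits(fit, "lof_model"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(fit$x)) stop("feature count mismatch", call. = FALSE)
  if (nrow(x) == 0) return(numeric(0))
  # cross-distances test x train
  cross <- sqrt(pmax(
    outer(rowSums(x^2), rowSums(fit$x^2), "+") - 2 * tcrossprod(x, fit$x),
    0
  ))
  vapply(seq_len(nrow(x)), function(i) {
    nb <- order(cross[i, ])[seq_len(fit$k)]
    reach <- pmax(fit$kdist[nb], cross[i, nb])
    m <- mean(reach)
    lrd_p <- if (m == 0) Inf else 1 / m
    r <- mean(fit$lrd[nb]) / lrd_p
    if (is.nan(r)) 1 else r
  }, 0)
}
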
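#' Fit an isolation forest
#'
#' Random partition trees on subsamples of the training rows; points that
#' isolate in short average paths score as anomalies. Scores follow the
#' standard normalization `s = 2^(-E[h]/c(psi))`, so they lie in (0, 1]
#' with higher = more anomalous.
#'
#' @param x numeric training matrix.
#' @param n_trees number of isolation trees.
#' @param sample_size subsample size per tree (capped at `nrow(x)`).
#' @param seed integer seed for the tree construction.
#' @return an object of class `iforest`.
#' @export
iforest_fit <- function(x, n_trees = 500, sample_size = 256, seed = 1L) {
  x <- as.matrix(x)
  forest <- with_seed(
    seed,
    iforest_build(x, as.integer(n_trees), as.integer(sample_size))
  )
  structure(list(forest = forest, p = ncol(x)), class = "iforest")
}

#' @rdname iforest_fit
#' @param fit an `iforest` object.
#' @return `iforest_score`: anomaly scores in (0, 1], one per row of `x`.
#' @export
iforest_score <- function(fit, x) {
  stopifnot(inherits(fit, "iforest"))
  x <- as.matrix(x)
  if (ncol(x) != fit$p) stop("feature count mismatch", call. = FALSE)
  if (nrow(x) == 0) return(numeric(0))
  as.numeric(iforest_path_scores(fit$forest, x))
}
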
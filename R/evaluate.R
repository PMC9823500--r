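#' Confusion counts with legitimate user as the positive class
#'
#' @param y_true,y_pred binary (0/1) label vectors of equal length; 1 means
#'   legitimate user.
#' @return list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1) stop("need at least one row", call. = FALSE)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  list(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0)
  )
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (0/0); returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Precision, recall, F1, accuracy and false positive rate
#'
#' The security/usability vocabulary of biometric verification: precision
#' and FPR measure how often impostors get in (security); recall measures
#' how often the legitimate user gets in (usability). Ratios with a zero
#' denominator return 0 with a warning, so degenerate reject-all or
#' accept-all runs still produce finite tables.
#'
#' @param counts a [confusion_counts()] result.
#' @return named numeric vector: `precision`, `recall`, `f1`, `accuracy`,
#'   `fpr`, all in `[0, 1]`.
#' @export
classification_metrics <- function(counts) {
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total < 1) stop("empty confusion table", call. = FALSE)
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  c(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (counts$tp + counts$tn) / total,
    fpr = safe_ratio(counts$fp, counts$fp + counts$tn, "fpr")
  )
}

#' ROC curve, AUC and equal error rate from continuous scores
#'
#' The curve is built by threshold enumeration over the unique scores
#' (predict 1 when `score >= threshold`), with the (0,0) and (1,1)
#' endpoints always included. AUC is the trapezoid-rule area. The EER is
#' the operating point where the false positive rate equals the false
#' rejection rate `1 - tpr`, linearly interpolated between the bracketing
#' thresholds on the ROC polyline.
#'
#' @param y_true binary labels (1 = legitimate); both classes must be
#'   present.
#' @param scores finite numeric scores, higher = more legitimate.
#' @return list with `auc`, `eer` and `curve` (data.frame `threshold`,
#'   `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc_eer(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))[c("auc", "eer")]
roc_auc_eer <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / n_neg, 0)
  thr <- c(Inf, thr)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    thr <- c(thr, -Inf)
    tpr <- c(tpr, 1)
    fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  # EER: zero of g = fpr - (1 - tpr) along the polyline
  g <- fpr - (1 - tpr)
  i <- which(g >= 0)[1]
  eer <- if (g[i] == 0 || i == 1) {
    fpr[i]
  } else {
    t <- g[i - 1] / (g[i - 1] - g[i])
    fpr[i - 1] + t * (fpr[i] - fpr[i - 1])
  }
  list(
    auc = auc, eer = eer,
    curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  )
}

#' Evaluate a trained model on one split's test partition
#'
#' @param model a [train_model()] result.
#' @param split the `split_bundle` whose `test` partition to score.
#' @return named numeric vector with `precision`, `recall`, `f1`,
#'   `accuracy`, `fpr`, and for score-producing (multi-class) kinds also
#'   `auc` and `eer`.
#' @export
evaluate_model <- function(model, split) {
  labels <- predict(model, split$test$x)
  out <- classification_metrics(confusion_counts(split$test$y, labels))
  if (model$spec$kind %in% MC_KINDS) {
    sc <- predict(model, split$test$x, type = "score")
    roc <- roc_auc_eer(split$test$y, sc)
    out <- c(out, auc = roc$auc, eer = roc$eer)
  }
  out
}
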
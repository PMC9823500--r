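MC_KINDS <- c("svm", "rf", "knn")
OC_KINDS <- c("oc_svm", "iforest", "lof")

#' Declarative description of one of the six classifiers
#'
#' Defaults follow the reference configuration: SVM with an RBF kernel and
#' a 10-fold cross-validated grid `C = {0.1, 1, 10, 100, 1000}` x
#' `gamma = {auto, scale, 0.001, 0.01, 0.1, 1, 10, 100}`; random forest and
#' isolation forest with 500 estimators; k = 25 neighbours for KNN and LOF;
#' `nu`/`contamination` defaulting to 0.5 for the one-class kinds. Only the
#' fields relevant to `kind` may be supplied.
#'
#' @param kind one of `"svm"`, `"rf"`, `"knn"` (multi-class) or
#'   `"oc_svm"`, `"iforest"`, `"lof"` (one-class).
#' @param ... kind-specific overrides: `C_grid`, `gamma_grid`, `cv_folds`
#'   (svm); `n_estimators` (rf, iforest); `k_neighbors` (knn, lof);
#'   `gamma`, `nu` (oc_svm); `contamination` (iforest, lof); `seed` (any).
#' @return an object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("iforest", contamination = 0.3)
classifier_spec <- function(kind, ...) {
  kind <- match.arg(kind, c(MC_KINDS, OC_KINDS))
  defaults <- switch(kind,
    svm = list(
      C_grid = c(0.1, 1, 10, 100, 1000),
      gamma_grid = list("auto", "scale", 0.001, 0.01, 0.1, 1, 10, 100),
      cv_folds = 10
    ),
    rf = list(n_estimators = 500),
    knn = list(k_neighbors = 25),
    oc_svm = list(nu = 0.5, gamma = "scale"),
    iforest = list(n_estimators = 500, contamination = 0.5),
    lof = list(k_neighbors = 25, contamination = 0.5)
  )
  defaults$seed <- NULL
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(defaults), "seed"))
  if (length(unknown)) {
    stop(
      "field(s) not relevant to kind '", kind, "': ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  spec <- utils::modifyList(defaults, dots)
  spec$kind <- kind
  if (!is.null(spec$nu) && (spec$nu <= 0 || spec$nu > 1)) {
    stop("nu must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(spec$contamination) &&
      (spec$contamination <= 0 || spec$contamination > 0.5)) {
    stop("contamination must be in (0, 0.5]", call. = FALSE)
  }
  structure(spec, class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  fields <- setdiff(names(unclass(x)), "kind")
  cat("<classifier_spec>", x$kind, "\n")
  for (f in fields) {
    v <- x[[f]]
    cat(
      " ", f, "=",
      if (is.list(v)) paste(unlist(v), collapse = ",") else paste(v, collapse = ","),
      "\n"
    )
  }
  invisible(x)
}

resolve_gamma <- function(gamma, x) {
  if (is.character(gamma)) {
    p <- ncol(x)
    switch(gamma,
      auto = 1 / p,
      scale = {
        v <- mean(x^2) - mean(x)^2
        if (v <= 0) 1 / p else 1 / (p * v)
      },
      stop("unknown gamma token: ", gamma, call. = FALSE)
    )
  } else {
    as.numeric(gamma)
  }
}

# 10-fold CV over C x gamma, selection metric accuracy; ties break toward
# smaller C then smaller resolved gamma (the less complex model).
svm_grid_search <- function(x, y, spec, seed) {
  folds_k <- min(spec$cv_folds, min(table(y)))
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- with_seed(
      derive_seed(seed, "folds", cls),
      sample(rep_len(seq_len(folds_k), length(idx)))
    )
  }
  grid <- expand.grid(
    Ci = seq_along(spec$C_grid), gi = seq_along(spec$gamma_grid)
  )
  acc <- numeric(nrow(grid))
  gammas <- vapply(spec$gamma_grid, resolve_gamma, 0, x = x)
  yf <- factor(y, levels = c(0, 1))
  for (r in seq_len(nrow(grid))) {
    cost <- spec$C_grid[grid$Ci[r]]
    gamma <- gammas[grid$gi[r]]
    correct <- 0
    for (f in seq_len(folds_k)) {
      tr <- fold_id != f
      fit <- e1071::svm(
        x = x[tr, , drop = FALSE], y = yf[tr], kernel = "radial",
        cost = cost, gamma = gamma, scale = FALSE
      )
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    acc[r] <- correct / length(y)
  }
  ord <- order(-acc, spec$C_grid[grid$Ci], gammas[grid$gi])
  best <- grid[ord[1], ]
  list(
    C = spec$C_grid[best$Ci],
    gamma = gammas[best$gi],
    gamma_label = as.character(spec$gamma_grid[[best$gi]]),
    cv_accuracy = acc[ord[1]]
  )
}

#' Train one classifier on a split
#'
#' All six kinds share one contract: models are fitted on the (z-score
#' standardized) train partition and later emit labels in `{0, 1}` with 1 =
#' legitimate user. One-class kinds train on positives only and adapt
#' their native inlier/outlier output; `iforest` and `lof` threshold their
#' anomaly scores at the `1 - contamination` quantile of the training
#' scores. The SVM tunes `C` and `gamma` by cross-validated accuracy on
#' the train partition; LOF runs in novelty mode.
#'
#' @param spec a [classifier_spec()].
#' @param split a `split_bundle` whose mode matches the spec kind
#'   (one-class kinds need a one-class split).
#' @return an object of class `eegauth_model` with fields `spec`, `fit`,
#'   `chosen_hyperparams`, and the fitted standardization.
#' @export
train_model <- function(spec, split) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(split, "split_bundle"))
  oc <- spec$kind %in% OC_KINDS
  if (oc && split$mode != "one_class") {
    stop("one-class kind '", spec$kind, "' requires a one-class split",
      call. = FALSE
    )
  }
  if (!oc && split$mode != "multi_class") {
    stop("multi-class kind '", spec$kind, "' requires a multi-class split",
      call. = FALSE
    )
  }
  x <- split$train$x
  y <- split$train$y
  if (!oc && length(unique(y)) < 2) {
    stop("multi-class training needs both labels present", call. = FALSE)
  }
  seed <- spec$seed %||% split$seed %||% 1L
  std <- standardize_features(x)
  xs <- std$train
  chosen <- list()
  fit <- switch(spec$kind,
    svm = {
      chosen <- svm_grid_search(xs, y, spec, seed)
      e1071::svm(
        x = xs, y = factor(y, levels = c(0, 1)), kernel = "radial",
        cost = chosen$C, gamma = chosen$gamma, scale = FALSE
      )
    },
    rf = with_seed(
      derive_seed(seed, "rf"),
      randomForest::randomForest(
        x = xs, y = factor(y, levels = c(0, 1)), ntree = spec$n_estimators
      )
    ),
    knn = list(x = xs, y = y, k = spec$k_neighbors),
    oc_svm = e1071::svm(
      x = xs, type = "one-classification", kernel = "radial",
      nu = spec$nu, gamma = resolve_gamma(spec$gamma, xs), scale = FALSE
    ),
    iforest = {
      f <- iforest_fit(
        xs,
        n_trees = spec$n_estimators,
        sample_size = min(256, nrow(xs)), seed = derive_seed(seed, "iforest")
      )
      train_scores <- iforest_score(f, xs)
      f$threshold <- as.numeric(
        quantile(train_scores, 1 - spec$contamination)
      )
      f
    },
    lof = {
      f <- lof_fit(xs, k = spec$k_neighbors)
      f$threshold <- as.numeric(
        quantile(lof_train_scores(f), 1 - spec$contamination)
      )
      f
    }
  )
  structure(
    list(
      spec = spec, fit = fit, chosen_hyperparams = chosen,
      center = std$center, scale = std$scale,
      feature_names = colnames(x)
    ),
    class = "eegauth_model"
  )
}

check_schema <- function(model, x) {
  nm <- colnames(x)
  if (is.null(nm) && ncol(x) == length(model$feature_names)) return(invisible())
  missing <- setdiff(model$feature_names, nm)
  extra <- setdiff(nm, model$feature_names)
  if (length(missing) || length(extra) ||
      !identical(nm, model$feature_names)) {
    stop(
      "feature schema mismatch",
      if (length(missing)) {
        paste0("; missing: ", paste(head(missing, 5), collapse = ", "))
      },
      if (length(extra)) {
        paste0("; extra: ", paste(head(extra, 5), collapse = ", "))
      },
      call. = FALSE
    )
  }
}

#' Predict authentication labels (or scores) for new segments
#'
#' Labels are always in `{0, 1}` with 1 = authenticated as the legitimate
#' user; native one-class conventions (+1 inlier / -1 outlier, anomaly
#' scores) are mapped onto that contract. Continuous scores
#' (`type = "score"`, higher = more legitimate) are available for the
#' multi-class kinds only: the SVM's decision value, the random forest's
#' class-1 vote fraction, and the KNN neighbour vote fraction.
#'
#' @param object an `eegauth_model`.
#' @param newdata `feature_matrix` or numeric matrix with the training
#'   columns.
#' @param type `"label"` (default) or `"score"`.
#' @param ... unused.
#' @return integer labels or numeric scores, one per row.
#' @export
predict.eegauth_model <- function(object, newdata, type = c("label", "score"),
                                  ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  check_schema(object, x)
  if (nrow(x) == 0) {
    return(if (type == "label") integer(0) else numeric(0))
  }
  xs <- sweep(x, 2, object$center)
  xs <- sweep(xs, 2, ifelse(object$scale > 0, object$scale, 1), "/")
  xs[, object$scale == 0] <- 0
  kind <- object$spec$kind
  if (type == "score" && kind %in% OC_KINDS) {
    stop("scores are not exposed for one-class models", call. = FALSE)
  }
  switch(kind,
    svm = {
      pred <- predict(object$fit, xs, decision.values = TRUE)
      if (type == "label") {
        as.integer(as.character(pred))
      } else {
        dv <- attr(pred, "decision.values")
        # orient so that higher = class "1"
        if (identical(colnames(dv)[1], "1/0")) dv[, 1] else -dv[, 1]
      }
    },
    rf = {
      if (type == "label") {
        as.integer(as.character(predict(object$fit, xs)))
      } else {
        unname(predict(object$fit, xs, type = "prob")[, "1"])
      }
    },
    knn = {
      k <- min(object$fit$k, nrow(object$fit$x))
      pred <- class::knn(
        train = object$fit$x, test = xs,
        cl = factor(object$fit$y, levels = c(0, 1)), k = k, prob = TRUE
      )
      if (type == "label") {
        as.integer(as.character(pred))
      } else {
        p_win <- attr(pred, "prob")
        ifelse(pred == "1", p_win, 1 - p_win)
      }
    },
    oc_svm = as.integer(predict(object$fit, xs)),
    iforest = {
      s <- iforest_score(object$fit, xs)
      as.integer(s <= object$fit$threshold)
    },
    lof = {
      s <- lof_score(object$fit, xs)
      as.integer(s <= object$fit$threshold)
    }
  )
}

#' @export
print.eegauth_model <- function(x, ...) {
  cat(
    "<eegauth_model>", x$spec$kind, "on", length(x$feature_names),
    "features\n"
  )
  if (length(x$chosen_hyperparams)) {
    cat(
      "  tuned:",
      paste(names(x$chosen_hyperparams),
        vapply(x$chosen_hyperparams, function(v) paste(format(v), collapse = ","), ""),
        sep = "=", collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}
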
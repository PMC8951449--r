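#' Fisher score of each feature
#'
#' Univariate discriminability ratio
#' `F(i) = ((xbar_i+ - xbar_i)^2 + (xbar_i- - xbar_i)^2) /
#'         (var_i+ + var_i-)`
#' where `xbar_i` is the overall mean and the denominator sums the unbiased
#' within-class variances. Larger scores mark more discriminative features.
#'
#' @param features subjects x m numeric matrix.
#' @param labels vector of +1 / -1 class labels.
#' @return numeric vector of m non-negative scores (0, with a warning, for
#'   features whose pooled denominator is zero).
#' @export
fisher_score <- function(features, labels) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 / -1")
  if (sum(y == 1) < 2 || sum(y == -1) < 2)
    stop("need at least 2 subjects per class")
  xp <- x[y == 1, , drop = FALSE]
  xn <- x[y == -1, , drop = FALSE]
  m_all <- colMeans(x)
  mp <- colMeans(xp); mn <- colMeans(xn)
  vp <- apply(xp, 2, stats::var); vn <- apply(xn, 2, stats::var)
  num <- (mp - m_all)^2 + (mn - m_all)^2
  den <- vp + vn
  out <- num / den
  if (any(den == 0)) {
    warning("feature(s) with zero within-class variance scored 0")
    out[den == 0] <- 0
  }
  out
}

#' Classification metrics from predictions and decision values
#'
#' Class +1 is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). AUC is the Mann-Whitney rank statistic of
#' the decision values (midranks, so constant decision values give 0.5).
#'
#' @param truth,predicted vectors of +1 / -1 labels.
#' @param decision_values real-valued scores, larger favouring class +1.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
classification_metrics <- function(truth, predicted, decision_values) {
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(decision_values))
  if (length(unique(truth)) < 2) stop("both classes must appear in `truth`")
  tp <- sum(truth == 1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == -1)
  tn <- sum(truth == -1 & predicted == -1)
  fp <- sum(truth == -1 & predicted == 1)
  n1 <- sum(truth == 1); n0 <- sum(truth == -1)
  rk <- rank(decision_values)
  auc <- (sum(rk[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       auc = auc)
}

stratified_folds <- function(y, n_folds) {
  # fold assignment balanced within each class; caller controls the RNG
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

standardize_train <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdv, "/"))
}

linear_svm_fit <- function(x, y, cost) {
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  list(fit = fit, w = w)
}

linear_svm_predict <- function(model, x) {
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  dec <- drop(attr(pr, "decision.values"))
  # orient decision values so that larger means class +1
  if (identical(colnames(attr(pr, "decision.values"))[1], "-1/1")) dec <- -dec
  list(class = as.integer(as.character(pr)), decision = dec)
}

inner_cv_choose_k <- function(x, y, k_grid, cost, n_inner = 5L) {
  # pick the retained-feature count by inner stratified CV on the training
  # fold only; ties go to the smaller k
  n_inner <- min(n_inner, min(table(y)))
  fold <- stratified_folds(y, n_inner)
  acc <- vapply(k_grid, function(k) {
    hits <- 0
    for (f in seq_len(n_inner)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2) return(NA_real_)
      # constant features (e.g. the zero diagonal of flattened
      # matrices) score 0 and are never selected; no need to warn here
      sc <- suppressWarnings(fisher_score(x[tr, , drop = FALSE], y[tr]))
      keep <- order(sc, decreasing = TRUE)[seq_len(k)]
      st <- standardize_train(x[tr, keep, drop = FALSE],
                              x[te, keep, drop = FALSE])
      mod <- linear_svm_fit(st$train, y[tr], cost)
      hits <- hits + sum(linear_svm_predict(mod, st$test)$class == y[te])
    }
    hits / length(y)
  }, numeric(1))
  k_grid[which.max(acc)]
}

#' F-score ranked linear SVM under nested cross-validation
#'
#' Stratified `n_folds`-fold cross-validation. Inside every fold, strictly
#' on the training subjects only: features are standardized by the training
#' mean/SD, ranked by Fisher score, the retained count k is chosen from
#' `k_grid` by inner 5-fold accuracy, and a linear SVM (cost `C`) is trained
#' on the top-k features. Held-out subjects are predicted with the
#' training-fold scaling and selection. Pooled metrics and AUC come from the
#' concatenated held-out decision values.
#'
#' @param table a [feature_table()].
#' @param n_folds number of outer folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param k_grid candidate retained-feature counts; entries above the
#'   feature count are clipped with a warning.
#' @param cost SVM regularization parameter C (default 1).
#' @return object of class `classification_result`: `folds` (per-fold test
#'   indices, selected features, k, weights, metrics), `pooled` metrics
#'   (accuracy/sensitivity/specificity/AUC), `truth`, `predicted`,
#'   `decision_values`, `importance` (see [feature_importance()]).
#' @export
crossvalidated_svm <- function(table, n_folds = 10L, seed = 1L,
                               k_grid = c(10L, 25L, 50L, 100L, 200L, Inf),
                               cost = 1) {
  x <- table$x; y <- table$y
  if (min(base::table(y)) < n_folds)
    stop("need at least n_folds subjects per class")
  m <- ncol(x)
  k_grid[!is.finite(k_grid)] <- m     # Inf means "all features"
  if (any(k_grid > m)) {
    warning("k_grid entries above the feature count were clipped to ", m)
    k_grid <- pmin(k_grid, m)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, n_folds)
  folds <- vector("list", n_folds)
  pred <- integer(length(y)); dec <- numeric(length(y))
  imp_sum <- numeric(m)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    k <- inner_cv_choose_k(x[tr, , drop = FALSE], y[tr], k_grid, cost = cost)
    sc <- suppressWarnings(fisher_score(x[tr, , drop = FALSE], y[tr]))
    keep <- order(sc, decreasing = TRUE)[seq_len(k)]
    st <- standardize_train(x[tr, keep, drop = FALSE],
                            x[te, keep, drop = FALSE])
    mod <- linear_svm_fit(st$train, y[tr], cost)
    out <- linear_svm_predict(mod, st$test)
    pred[te] <- out$class
    dec[te] <- out$decision
    fold_metrics <- if (length(unique(y[te])) == 2) {
      classification_metrics(y[te], out$class, out$decision)
    } else NULL
    # importance of the selected features: w_j * sum_i y_i x_ij over the
    # training subjects (standardized features)
    imp <- mod$w * colSums(y[tr] * st$train)
    imp_sum[keep] <- imp_sum[keep] + imp
    folds[[f]] <- list(test = te, k = k, selected = keep, w = mod$w,
                       metrics = fold_metrics)
  }
  pooled <- classification_metrics(y, pred, dec)
  importance <- imp_sum / n_folds
  names(importance) <- colnames(x)
  structure(list(folds = folds, pooled = pooled, truth = y,
                 predicted = pred, decision_values = dec,
                 importance = importance, feature_set = table$feature_set,
                 positive_class = "+1 (GE)"),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<classification_result> %s features, %d folds\n", x$feature_set,
    length(x$folds)))
  cat(sprintf(
    "  pooled accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f\n",
    100 * p$accuracy, 100 * p$sensitivity, 100 * p$specificity, p$auc))
  cat("  positive class:", x$positive_class, "\n")
  invisible(x)
}

#' Ranked feature importance of a fitted classifier
#'
#' Importance of feature j is the fold-average of
#' `w_j * sum_i y_i x_ij` over the training subjects of each fold (weights
#' of unselected features count as 0), signed as computed -- the sign
#' carries the direction of group separation.
#'
#' @param result a [crossvalidated_svm()] result.
#' @param top number of rows to return (default all nonzero).
#' @return data frame `feature`, `importance`, sorted by absolute
#'   importance.
#' @export
feature_importance <- function(result, top = NULL) {
  if (is.null(result$importance)) stop("result carries no trained folds")
  imp <- result$importance
  ord <- order(abs(imp), decreasing = TRUE)
  out <- data.frame(feature = names(imp)[ord], importance = imp[ord],
                    row.names = NULL)
  if (is.null(top)) out <- out[out$importance != 0, , drop = FALSE]
  else out <- utils::head(out, top)
  out
}
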
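# Nested cross-validation utilities: fivefold internal early stopping,
# stratified 10-fold outer evaluation, and leave-one-feature-out importance.

make_folds <- function(n, k, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, n)
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

regression_strata <- function(y, n_bins = 10L) {
  br <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1L)))
  as.integer(cut(y, br, include.lowest = TRUE))
}

#' Select the number of boosting stages by internal cross-validation
#'
#' Splits the (training) data into `k` internal folds, grows an ensemble of
#' `params$M_max` stages on each training part, tracks the stagewise
#' validation loss (mean squared error for regression, misclassification
#' rate for classification), and returns the stage minimising the mean
#' validation loss (ties resolved towards the smallest ensemble). Only ever
#' call this on an outer-training split: it must not see outer test cells.
#'
#' @param X feature matrix.
#' @param y target (numeric) or labels (character/factor).
#' @param params [boost_params()]; `M_max` bounds the search.
#' @param k internal folds (default 5).
#' @param task `"regression"` or `"classification"`.
#' @param seed RNG seed for fold assignment.
#' @return selected number of stages `M*`.
#' @export
internal_cv_stopping <- function(X, y, params = boost_params(),
                                 k = 5L, task = c("regression",
                                                  "classification"),
                                 seed = 1L) {
  task <- match.arg(task)
  n <- nrow(X)
  set.seed(seed)
  strata <- if (task == "regression") regression_strata(y)
            else as.character(y)
  fold <- make_folds(n, k, strata)
  M_max <- params$M_max
  loss <- matrix(NA_real_, k, M_max)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (task == "regression") {
      fit <- fit_lsboost_fixed(X[tr, , drop = FALSE], y[tr], M_max, params)
      staged <- staged_predict_lsboost(fit, X[te, , drop = FALSE])
      loss[f, ] <- colMeans((staged - y[te])^2)
    } else {
      p2 <- params; p2$M <- M_max
      fit <- fit_rusboost(X[tr, , drop = FALSE], y[tr], p2,
                          seed = seed + f)
      staged <- staged_predict_rusboost(fit, X[te, , drop = FALSE])
      loss[f, seq_len(ncol(staged))] <- colMeans(staged != y[te])
      if (ncol(staged) < M_max)
        loss[f, (ncol(staged) + 1L):M_max] <- loss[f, ncol(staged)]
    }
  }
  mean_loss <- colMeans(loss)
  which.min(mean_loss)   # first minimum = smallest M on ties
}

# Cells x stages matrix of cumulative-vote class predictions.
staged_predict_rusboost <- function(object, X) {
  df <- as_feature_df(X)
  votes <- matrix(0, nrow(X), length(object$classes),
                  dimnames = list(NULL, object$classes))
  out <- matrix(NA_character_, nrow(X), object$M)
  for (m in seq_len(object$M)) {
    pred <- predict_rpart_class(object$trees[[m]], df, object$classes)
    ij <- cbind(seq_len(nrow(X)), match(pred, object$classes))
    votes[ij] <- votes[ij] + object$alpha[m]
    out[, m] <- object$classes[apply(votes, 1, which.max)]
  }
  out
}

#' Stratified k-fold cross-validation of the boosted learners
#'
#' Folds are stratified by class label (classification) or target decile
#' (regression); every cell lands in exactly one test fold. The per-fold
#' metric is the Pearson correlation between predicted and true target
#' (regression) or the per-class true positive rate, the diagonal of the
#' fold confusion matrix over its row sums (classification). Classes absent
#' from a fold's test set yield an NA TPR for that fold, excluded from the
#' mean with a warning.
#'
#' @param X feature matrix.
#' @param truth numeric target or class labels.
#' @param k folds (default 10).
#' @param task `"regression"` or `"classification"`.
#' @param params [boost_params()]. A fixed `params$M` avoids the nested
#'   internal-stopping cost; `M = NULL` runs fivefold internal stopping
#'   inside every outer training split.
#' @param seed RNG seed (folds, stage subsampling).
#' @return object of class `cv_report`: per-fold metric values, mean, s.d.,
#'   fold assignment, and the pooled confusion matrix for classification.
#' @export
cross_validate <- function(X, truth, k = 10L,
                           task = c("regression", "classification"),
                           params = boost_params(), seed = 1L) {
  task <- match.arg(task)
  n <- nrow(X)
  if (n < k) stop("need at least k cells")
  set.seed(seed)
  if (task == "regression") {
    if (n / k < 2) stop("regression folds need >= 2 cells (Pearson r undefined)")
    fold <- make_folds(n, k, regression_strata(truth))
  } else {
    truth <- as.character(truth)
    fold <- make_folds(n, k, truth)
  }
  per_fold <- NULL
  confusion <- NULL
  predictions <- if (task == "regression") numeric(n) else character(n)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (task == "regression") {
      fit <- fit_lsboost(X[tr, , drop = FALSE], truth[tr], params,
                         seed = seed * 1000L + f)
      pred <- predict(fit, X[te, , drop = FALSE])
      predictions[te] <- pred
      per_fold <- c(per_fold, cor(pred, truth[te]))
    } else {
      classes <- sort(unique(truth))
      if (length(unique(truth[tr])) < 2) {
        warning("training split of fold ", f,
                " holds a single class; fold skipped")
        per_fold <- cbind(per_fold, setNames(rep(NA_real_, length(classes)),
                                             classes))
        next
      }
      fit <- fit_rusboost(X[tr, , drop = FALSE], truth[tr], params,
                          seed = seed * 1000L + f)
      pred <- predict(fit, X[te, , drop = FALSE])
      predictions[te] <- pred
      cm <- table(factor(truth[te], classes), factor(pred, classes))
      tpr <- diag(cm) / rowSums(cm)
      per_fold <- cbind(per_fold, tpr)
      confusion <- if (is.null(confusion)) cm else confusion + cm
    }
  }
  if (task == "regression") {
    rep <- list(task = task, metric = "pearson_r", k = k, fold = fold,
                per_fold = per_fold, mean = mean(per_fold),
                sd = sd(per_fold), predictions = predictions)
  } else {
    if (anyNA(per_fold))
      warning("some classes were absent from some test folds; ",
              "their fold TPRs are excluded from the mean")
    rep <- list(task = task, metric = "per_class_tpr", k = k, fold = fold,
                per_fold = per_fold,
                mean = rowMeans(per_fold, na.rm = TRUE),
                sd = apply(per_fold, 1, sd, na.rm = TRUE),
                confusion = confusion, predictions = predictions)
  }
  structure(rep, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", x$k, x$metric))
  if (x$task == "regression") {
    cat(sprintf("  Pearson r = %.3f +/- %.3f (s.d. over folds)\n",
                x$mean, x$sd))
  } else {
    for (cl in names(x$mean))
      cat(sprintf("  TPR %-12s = %.3f +/- %.3f\n", cl, x$mean[cl], x$sd[cl]))
  }
  invisible(x)
}

# Scalar summary used by the importance analysis.
cv_scalar <- function(report)
  if (report$task == "regression") report$mean else mean(report$mean)

#' Leave-one-feature-out importance
#'
#' Re-runs cross-validation with each feature column removed in turn;
#' importance is the drop in the mean metric (Pearson r, or macro-averaged
#' per-class TPR) relative to the all-features baseline. Because many
#' morphological features are highly correlated, individual importances are
#' typically small even when a feature family is jointly informative;
#' category roll-ups (sums over manifest categories) are attached for that
#' reason.
#'
#' @param X feature matrix.
#' @param truth target or labels.
#' @param task `"regression"` or `"classification"`.
#' @param k folds.
#' @param params [boost_params()].
#' @param seed RNG seed (shared across runs so fold layouts match).
#' @param manifest optional manifest for category roll-ups.
#' @param baseline optional precomputed baseline `cv_report`.
#' @return data.frame (`feature`, `importance`, `category`) sorted by
#'   decreasing importance, with attribute `category_rollup`.
#' @export
lofo_importance <- function(X, truth, task = c("regression",
                                               "classification"),
                            k = 10L, params = boost_params(), seed = 1L,
                            manifest = NULL, baseline = NULL) {
  task <- match.arg(task)
  if (is.null(baseline))
    baseline <- cross_validate(X, truth, k, task, params, seed)
  base <- cv_scalar(baseline)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    rep_j <- cross_validate(X[, -j, drop = FALSE], truth, k, task, params,
                            seed)
    base - cv_scalar(rep_j)
  }, numeric(1))
  cat_map <- if (!is.null(manifest))
    manifest$category[match(colnames(X), manifest$name)] else
    rep(NA_character_, ncol(X))
  out <- data.frame(feature = colnames(X), importance = imp,
                    category = cat_map, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  if (!is.null(manifest))
    attr(out, "category_rollup") <-
      tapply(out$importance, out$category, sum)
  out
}
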
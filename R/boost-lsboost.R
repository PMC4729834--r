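# Least-squares gradient boosting with regression-tree weak learners.
# Each stage fits a shallow rpart tree to the current residuals (the
# negative gradient of squared-error loss) and is added with shrinkage nu.

#' Boosting hyper-parameters
#'
#' The original study delegates these to a black-box ensemble routine; the
#' defaults here are conventional gradient-boosting settings and are fully
#' configurable.
#'
#' @param M number of boosting stages; `NULL` selects it by fivefold
#'   internal cross-validation up to `M_max` (see
#'   [internal_cv_stopping()]).
#' @param M_max maximum stages considered by internal stopping.
#' @param nu shrinkage (learning rate) for regression boosting.
#' @param depth weak-learner tree depth.
#' @param min_leaf minimum observations per leaf.
#' @param undersample_ratio RUSBoost only: each larger class is cut to
#'   `ratio` times the minority class size per stage; `Inf` disables
#'   undersampling (plain multi-class AdaBoost).
#' @return named list of parameters.
#' @export
boost_params <- function(M = NULL, M_max = 200L, nu = 0.1, depth = 3L,
                         min_leaf = 10L, undersample_ratio = 1.0) {
  list(M = M, M_max = as.integer(M_max), nu = nu, depth = as.integer(depth),
       min_leaf = as.integer(min_leaf), undersample_ratio = undersample_ratio)
}

rpart_ctrl <- function(params)
  rpart::rpart.control(maxdepth = params$depth, minbucket = params$min_leaf,
                       minsplit = 2L * params$min_leaf, cp = 0, xval = 0L,
                       maxsurrogate = 0L, maxcompete = 0L)

as_feature_df <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- colnames(X)
  df
}

#' Fit a least-squares boosted regression ensemble
#'
#' Stagewise fit of shallow regression trees to the squared-error residuals,
#' starting from the training-target mean, with shrinkage `nu`. The number
#' of stages is `params$M` if given, otherwise chosen by fivefold internal
#' cross-validation on the training data only.
#'
#' @param X numeric feature matrix (cells x features, named columns).
#' @param y numeric target (e.g. integrated DNA stain intensity).
#' @param params [boost_params()].
#' @param seed RNG seed (internal-stopping fold assignment).
#' @return object of class `lsboost` with the weak learners, shrinkage,
#'   baseline, selected `M` and training metadata.
#' @export
fit_lsboost <- function(X, y, params = boost_params(), seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (nrow(X) < 20) stop("need at least 20 cells to fit")
  if (!all(is.finite(y))) stop("target must be finite")
  if (var(y) == 0) stop("zero-variance target")
  M <- params$M
  if (is.null(M)) {
    M <- internal_cv_stopping(X, y, params, k = 5L, task = "regression",
                              seed = seed)
  }
  fit_lsboost_fixed(X, y, M, params)
}

fit_lsboost_fixed <- function(X, y, M, params) {
  df <- as_feature_df(X)
  baseline <- mean(y)
  Fhat <- rep(baseline, nrow(X))
  trees <- vector("list", M)
  train_loss <- numeric(M)
  ctrl <- rpart_ctrl(params)
  for (m in seq_len(M)) {
    df$.resid <- y - Fhat
    tr <- rpart::rpart(.resid ~ ., data = df, method = "anova",
                       control = ctrl)
    trees[[m]] <- tr
    Fhat <- Fhat + params$nu * predict(tr, df)
    train_loss[m] <- mean((y - Fhat)^2)
  }
  structure(list(trees = trees, nu = params$nu, M = M, baseline = baseline,
                 feature_names = colnames(X), params = params,
                 train_loss = train_loss,
                 train_predictions = Fhat,
                 manifest_version = attr(X, "manifest_version") %||% NA),
            class = "lsboost")
}

check_features <- function(model, X) {
  if (!identical(colnames(X), model$feature_names))
    stop("feature columns do not match the model's training manifest")
}

#' Predict from a boosted regression ensemble
#'
#' @param object an `lsboost` model.
#' @param X feature matrix with the model's training columns.
#' @param M optionally truncate the ensemble to the first `M` stages.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.lsboost <- function(object, X, M = NULL, ...) {
  check_features(object, X)
  df <- as_feature_df(X)
  M <- M %||% object$M
  out <- rep(object$baseline, nrow(X))
  for (m in seq_len(M)) out <- out + object$nu * predict(object$trees[[m]], df)
  out
}

# Staged predictions: n x M matrix of cumulative predictions after each stage.
staged_predict_lsboost <- function(object, X) {
  df <- as_feature_df(X)
  out <- matrix(object$baseline, nrow(X), object$M)
  acc <- rep(object$baseline, nrow(X))
  for (m in seq_len(object$M)) {
    acc <- acc + object$nu * predict(object$trees[[m]], df)
    out[, m] <- acc
  }
  out
}
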
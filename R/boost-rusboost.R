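# Random-undersampling boosting for imbalanced multi-class problems.
# Multi-class AdaBoost (SAMME weight update) in which each stage's weak
# learner is trained on a class-balanced random undersample of the weighted
# training set, while the stage weight is computed from the weighted error
# on the FULL training set. Mitotic phases are rare (a few percent of
# cells); without undersampling, stagewise learners ignore them.

#' Fit a random-undersampling boosted classifier
#'
#' @param X numeric feature matrix (named columns).
#' @param labels factor or character class labels.
#' @param params [boost_params()]; `undersample_ratio` controls how far the
#'   larger classes are cut towards the smallest class per stage
#'   (1 = equal size, `Inf` = no undersampling, which reduces the
#'   algorithm to plain multi-class AdaBoost).
#' @param seed RNG seed for the per-stage undersampling draws.
#' @return object of class `rusboost` with stage learners, stage weights
#'   (`alpha`), the class list (training order, used for tie-breaks) and
#'   per-stage undersampling records.
#' @export
fit_rusboost <- function(X, labels, params = boost_params(M = 40L),
                         seed = 1L) {
  stopifnot(is.matrix(X), length(labels) == nrow(X))
  labels <- as.character(labels)
  classes <- unique(labels)
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes")
  M <- params$M %||% 40L
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as_feature_df(X)
  df$.label <- factor(labels, levels = classes)
  ctrl <- rpart_ctrl(params)
  trees <- vector("list", M)
  alpha <- numeric(M)
  samples <- vector("list", M)
  set.seed(seed)
  m_used <- 0L
  for (m in seq_len(M)) {
    idx <- undersample_indices(labels, params$undersample_ratio,
                               floor_n = params$min_leaf)
    tr <- rpart::rpart(.label ~ ., data = df[idx, , drop = FALSE],
                       weights = w[idx] / sum(w[idx]), method = "class",
                       control = ctrl)
    pred <- predict_rpart_class(tr, df, classes)
    miss <- pred != labels
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / K) next        # worse than chance: discard stage
    err <- max(err, 1e-10)
    a <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(a * miss)
    w <- w / sum(w)
    m_used <- m_used + 1L
    trees[[m_used]] <- tr
    alpha[m_used] <- a
    samples[[m_used]] <- idx
  }
  if (m_used == 0L) stop("no usable boosting stage (all weak learners at chance)")
  structure(list(trees = trees[seq_len(m_used)],
                 alpha = alpha[seq_len(m_used)],
                 classes = classes, M = m_used, params = params, seed = seed,
                 feature_names = colnames(X), samples = samples[seq_len(m_used)]),
            class = "rusboost")
}

# Per-stage undersample: classes larger than ratio * (smallest class size)
# are randomly cut down to that size; all of the smallest class is kept.
# The cap never drops below the weak learner's leaf size, so a 1-member
# class cannot starve the stage of training data.
undersample_indices <- function(labels, ratio = 1.0, floor_n = 10L) {
  if (!is.finite(ratio)) return(seq_along(labels))
  tab <- table(labels)
  n_min <- min(tab)
  cap <- max(ceiling(ratio * n_min), floor_n)
  unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > cap) sample(idx, cap) else idx
  }), use.names = FALSE)
}

predict_rpart_class <- function(tree, df, classes) {
  p <- predict(tree, df, type = "class")
  as.character(p)
}

#' Predict classes (and vote scores) from a RUSBoost ensemble
#'
#' Aggregates `alpha`-weighted stage votes; the predicted class is the
#' argmax, with ties broken in favour of the class listed first in the
#' model's class list.
#'
#' @param object an `rusboost` model.
#' @param X feature matrix with the model's training columns.
#' @param type `"class"` (default) or `"votes"` for the score matrix.
#' @param ... unused.
#' @return character vector of classes, or cells x classes vote matrix.
#' @export
predict.rusboost <- function(object, X, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  check_features(object, X)
  df <- as_feature_df(X)
  votes <- matrix(0, nrow(X), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in seq_len(object$M)) {
    pred <- predict_rpart_class(object$trees[[m]], df, object$classes)
    votes[cbind(seq_len(nrow(X)), match(pred, object$classes))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, object$classes))] +
      object$alpha[m]
  }
  if (type == "votes") return(votes)
  object$classes[apply(votes, 1, which.max)]   # which.max: first-listed wins ties
}
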
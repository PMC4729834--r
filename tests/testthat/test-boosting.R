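make_reg_data <- function(n = 300, p = 6, seed = 1, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 2 * X[, 1] - X[, 2] + noise * rnorm(n)
  list(X = X, y = y)
}

test_that("LSBoost drives training error to zero on a realizable target", {
  set.seed(1)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  d <- list(X = X, y = 2 * X[, 1])           # noise-free single feature
  fit <- fit_lsboost(d$X, d$y, boost_params(M = 250), seed = 1)
  expect_gte(cor(fit$train_predictions, d$y), 0.999)
  expect_true(all(diff(fit$train_loss) <= 1e-12))  # loss never increases
  expect_equal(fit$baseline, mean(d$y))
})

test_that("LSBoost rejects degenerate inputs", {
  d <- make_reg_data(30, 3)
  expect_error(fit_lsboost(d$X, rep(1, 30), boost_params(M = 5)),
               "zero-variance")
  expect_error(fit_lsboost(d$X[1:10, ], d$y[1:10], boost_params(M = 5)),
               "at least 20")
  expect_error(fit_lsboost(d$X, c(d$y[-1], NA), boost_params(M = 5)),
               "finite")
})

test_that("predictions are deterministic and manifest-checked", {
  d <- make_reg_data(100, 4)
  fit <- fit_lsboost(d$X, d$y, boost_params(M = 20), seed = 3)
  expect_equal(predict(fit, d$X), fit$train_predictions, tolerance = 1e-12)
  Xbad <- d$X; colnames(Xbad) <- paste0("g", 1:4)
  expect_error(predict(fit, Xbad), "manifest")
})

test_that("internal stopping detects overfitting on pure noise", {
  set.seed(5)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y_noise <- rnorm(200)
  p <- boost_params(M_max = 60)
  m_noise <- internal_cv_stopping(X, y_noise, p, task = "regression", seed = 2)
  expect_lte(m_noise, 6)             # <= 10% of M_max
  y_clean <- 2 * X[, 1] - X[, 2]
  m_clean <- internal_cv_stopping(X, y_clean, p, task = "regression", seed = 2)
  expect_gte(m_clean, 30)            # learnable target keeps improving
  # determinism: same seed, same selection
  expect_identical(m_noise,
                   internal_cv_stopping(X, y_noise, p, task = "regression",
                                        seed = 2))
})

test_that("permuted targets cross-validate to zero correlation", {
  d <- make_reg_data(300, 6, seed = 7, noise = 0.3)
  set.seed(11)
  y_perm <- sample(d$y)
  cv <- cross_validate(d$X, y_perm, k = 10, task = "regression",
                       params = boost_params(M = 25), seed = 4)
  expect_lte(abs(cv$mean), 0.1)
})

test_that("RUSBoost separates balanced classes and respects class lists", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60 * 3, 0), 60, 3), matrix(rnorm(60 * 3, 4), 60, 3))
  colnames(X) <- paste0("f", 1:3)
  lab <- rep(c("a", "b"), each = 60)
  fit <- fit_rusboost(X, lab, boost_params(M = 10), seed = 1)
  pred <- predict(fit, X)
  expect_equal(as.numeric(tapply(pred == lab, lab, mean)), c(1, 1))
  expect_true(all(unique(pred) %in% fit$classes))
  expect_error(fit_rusboost(X, rep("a", 120), boost_params(M = 5)),
               "2 classes")
})

test_that("undersampling rescues a rare overlapping minority class", {
  # 1% minority, two informative dimensions among eight noise ones:
  # separable enough for a balanced learner, invisible to an unweighted one
  set.seed(13)
  n_min <- 40; n_maj <- 3960; p_noise <- 8
  X <- rbind(cbind(matrix(rnorm(n_maj * 2), n_maj, 2),
                   matrix(rnorm(n_maj * p_noise), n_maj, p_noise)),
             cbind(matrix(rnorm(n_min * 2, mean = 2.4), n_min, 2),
                   matrix(rnorm(n_min * p_noise), n_min, p_noise)))
  colnames(X) <- paste0("f", seq_len(2 + p_noise))
  lab <- c(rep("major", n_maj), rep("minor", n_min))
  cv_rus <- cross_validate(X, lab, k = 5, task = "classification",
                           params = boost_params(M = 30), seed = 6)
  cv_plain <- cross_validate(X, lab, k = 5, task = "classification",
                             params = boost_params(M = 30,
                                                   undersample_ratio = Inf),
                             seed = 6)
  expect_gte(cv_rus$mean[["minor"]], 0.85)
  expect_lte(cv_plain$mean[["minor"]], 0.6)
  expect_gte(cv_rus$mean[["minor"]] - cv_plain$mean[["minor"]], 0.3)
})

test_that("without undersampling RUSBoost equals a brute-force AdaBoost", {
  set.seed(17)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  lab <- c(rep("a", 18), rep("b", 14), rep("c", 8))
  X[lab == "b", 1] <- X[lab == "b", 1] + 1.5
  X[lab == "c", 2] <- X[lab == "c", 2] - 1.5
  fit <- fit_rusboost(X, lab,
                      boost_params(M = 8, undersample_ratio = Inf), seed = 2)
  oracle <- adaboost_oracle(X, lab, M = 8)
  expect_equal(fit$alpha, oracle$alphas, tolerance = 1e-10)
  expect_identical(predict(fit, X), oracle$predict(X))
})

test_that("cross-validation partitions every cell exactly once", {
  d <- make_reg_data(130, 4, seed = 19, noise = 0.5)
  cv <- cross_validate(d$X, d$y, k = 10, task = "regression",
                       params = boost_params(M = 10), seed = 8)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_equal(length(cv$fold), 130)           # one fold id per cell
  expect_length(cv$per_fold, 10)
  # stratified classification folds: each class spread over folds
  set.seed(21)
  Xc <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, paste0("f", 1:3)))
  labc <- rep(c("u", "v"), each = 100)
  Xc[labc == "v", ] <- Xc[labc == "v", ] + 8
  cvc <- cross_validate(Xc, labc, k = 5, task = "classification",
                        params = boost_params(M = 5), seed = 9)
  expect_true(all(table(cvc$fold, labc) == 20))
  expect_equal(unname(cvc$mean), c(1, 1))
  expect_equal(unname(cvc$sd), c(0, 0))
  expect_equal(sum(cvc$confusion), 200)
  # leave-one-out regression folds are rejected: r undefined on singletons
  expect_error(cross_validate(d$X, d$y, k = 130, task = "regression",
                              params = boost_params(M = 5), seed = 1),
               "Pearson")
})

test_that("seeded cross-validation reports are reproducible", {
  d <- make_reg_data(120, 4, seed = 23, noise = 0.4)
  cv1 <- cross_validate(d$X, d$y, k = 5, task = "regression",
                        params = boost_params(M = 15), seed = 12)
  cv2 <- cross_validate(d$X, d$y, k = 5, task = "regression",
                        params = boost_params(M = 15), seed = 12)
  expect_identical(cv1$fold, cv2$fold)
  expect_equal(cv1$per_fold, cv2$per_fold, tolerance = 1e-12)
})

test_that("leave-one-feature-out importance flags the right features", {
  set.seed(25)
  X <- matrix(rnorm(150 * 4), 150, 4,
              dimnames = list(NULL, c("signal", "dup", "noise", "flat")))
  X[, "dup"] <- X[, "signal"]
  X[, "flat"] <- 1
  y <- 3 * X[, "signal"] + 0.2 * rnorm(150)
  man <- data.frame(name = colnames(X),
                    category = c("a", "a", "b", "b"))
  base <- cross_validate(X, y, k = 4, task = "regression",
                         params = boost_params(M = 15), seed = 3)
  imp <- lofo_importance(X, y, task = "regression", k = 4,
                         params = boost_params(M = 15), seed = 3,
                         manifest = man, baseline = base)
  fold_sd <- base$sd
  expect_lte(abs(imp$importance[imp$feature == "flat"]), fold_sd)
  # a duplicated informative feature masks its copy
  expect_lte(abs(imp$importance[imp$feature == "dup"]), fold_sd)
  expect_lte(abs(imp$importance[imp$feature == "signal"]), fold_sd)
  rollup <- attr(imp, "category_rollup")
  expect_equal(sum(rollup), sum(imp$importance), tolerance = 1e-12)
  expect_true(all(diff(imp$importance) <= 1e-12))   # sorted descending
})

test_that("models serialize losslessly to versioned JSON", {
  d <- make_reg_data(80, 3, seed = 27)
  fit <- fit_lsboost(d$X, d$y, boost_params(M = 8), seed = 1)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(fit, path)
  back <- load_model(path)
  expect_s3_class(back, "lsboost")
  expect_equal(predict(back, d$X), predict(fit, d$X), tolerance = 1e-12)
  expect_error(load_model({
    p2 <- file.path(withr::local_tempdir(), "x.json")
    jsonlite::write_json(list(format = "other"), p2, auto_unbox = TRUE)
    p2
  }), "not a cytocycle model")
})
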
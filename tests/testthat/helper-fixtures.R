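# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small population + feature table for cheap structural tests.
small_population <- function() {
  cached("small_pop", generate_population(
    population_config(n_cells = 60, seed = 101)))
}

small_features <- function() {
  cached("small_ft", feature_table(small_population(), seed = 101))
}

# Study-scale population (default config) for the learning checks;
# expensive, so shared between the acceptance tests.
study_features <- function() {
  cached("study_ft", {
    pop <- generate_population(population_config(n_cells = 3000, seed = 2024))
    feature_table(pop, seed = 2024)
  })
}

# Render a single cell of a given phase/radius with near-zero noise.
render_fixture <- function(phase, radius = 10, seed = 1, noise_sd = 1e-3,
                           dna = if (phase == "G1") 2 else 4) {
  cfg <- population_config(n_cells = 1, seed = seed, noise_sd = noise_sd)
  state <- structure(list(phase = phase, t = 0, dna_content = dna,
                          nominal_radius = radius), class = "cell_state")
  set.seed(seed)
  render_cell(state, cfg, cell_id = paste0(phase, "_fix"))
}

# Reference DNA-content mixture: G1 at mu (content 2), G2/M at 2*mu
# (content 4), S uniform in content, all with multiplicative CV noise.
dna_mixture <- function(n, fractions = c(G1 = 0.60, S = 0.25, G2M = 0.15),
                        mu = 100, cv = 0.05) {
  comp <- sample(names(fractions), n, TRUE, fractions)
  content <- ifelse(comp == "G1", 2, ifelse(comp == "G2M", 4, runif(n, 2, 4)))
  (content / 2) * mu * (1 + rnorm(n, 0, cv))
}

# Brute-force multi-class AdaBoost (SAMME) oracle on rpart stumps;
# independent of the package's implementation.
adaboost_oracle <- function(X, labels, M, depth = 3L, min_leaf = 10L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  K <- length(classes)
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  df$.label <- factor(labels, levels = classes)
  votes <- matrix(0, n, K, dimnames = list(NULL, classes))
  ctrl <- rpart::rpart.control(maxdepth = depth, minbucket = min_leaf,
                               minsplit = 2L * min_leaf, cp = 0, xval = 0L,
                               maxsurrogate = 0L, maxcompete = 0L)
  preds <- list()
  alphas <- numeric(0)
  for (m in seq_len(M)) {
    tr <- rpart::rpart(.label ~ ., df, weights = w / sum(w),
                       method = "class", control = ctrl)
    pred <- as.character(predict(tr, df, type = "class"))
    miss <- pred != labels
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / K) next
    err <- max(err, 1e-10)
    a <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(a * miss)
    w <- w / sum(w)
    preds[[length(preds) + 1L]] <- pred
    alphas <- c(alphas, a)
  }
  list(predict = function(Xn) {
    # refit-free: only training-set predictions are exposed
    v <- matrix(0, n, K, dimnames = list(NULL, classes))
    for (m in seq_along(preds))
      v[cbind(seq_len(n), match(preds[[m]], classes))] <-
        v[cbind(seq_len(n), match(preds[[m]], classes))] + alphas[m]
    classes[apply(v, 1, which.max)]
  }, alphas = alphas)
}
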
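# End-to-end orchestration: simulate -> reshape -> segment -> features ->
# learn -> DNA-histogram deconvolution, with seeding, QC logging and a
# reproducible report.

#' Merge phase labels into the classification class schemes
#'
#' `"interphase"` (the canonical scheme): G1/S/G2 become one `interphase`
#' class while the four mitotic phases stay separate — single-stain DNA
#' content cannot distinguish G1/S/G2 individually, so interphase substates
#' are resolved by the regression arm, not the classifier.
#' `"blocked"`: additionally groups metaphase/anaphase/telophase into
#' `mitotic_other` (prophase stays separate) — after a mitotic block only
#' very few cells populate the individual late-mitotic classes, so they are
#' scored as one class.
#'
#' @param labels character phase labels.
#' @param scheme `"interphase"`, `"blocked"` or `"none"`.
#' @return character labels.
#' @export
merge_phase_labels <- function(labels,
                               scheme = c("interphase", "blocked", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(labels)
  out <- labels
  out[labels %in% c("G1", "S", "G2")] <- "interphase"
  if (scheme == "blocked")
    out[labels %in% c("metaphase", "anaphase", "telophase")] <- "mitotic_other"
  out
}

#' Default run configuration
#'
#' A single nested list drives the whole pipeline; the global `seed`
#' propagates deterministically to every stage (population seed, reshape
#' padding, fold assignment, undersampling).
#'
#' @param n_cells population size.
#' @param seed global seed.
#' @param tile standard tile side.
#' @param grid montage grid side.
#' @param block_shift mitotic-block mass for the treated arm (0 = none).
#' @param k_folds outer cross-validation folds.
#' @param regression_params,classification_params [boost_params()] for the
#'   two learners.
#' @param n_bins DNA histogram bins.
#' @param out_dir optional artifact directory.
#' @return named list (class `run_config`).
#' @export
run_config <- function(n_cells = 1000L, seed = 1L, tile = 55L, grid = 15L,
                       block_shift = 0,
                       k_folds = 10L,
                       regression_params = boost_params(M = 60L),
                       classification_params = boost_params(M = 40L),
                       n_bins = 64L, out_dir = NULL) {
  structure(list(n_cells = n_cells, seed = seed, tile = tile, grid = grid,
                 block_shift = block_shift, k_folds = k_folds,
                 regression_params = regression_params,
                 classification_params = classification_params,
                 n_bins = n_bins, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys override [run_config()] defaults; `regression_params` and
#' `classification_params` maps override [boost_params()] fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(y), setdiff(names(cfg),
                         c("regression_params", "classification_params"))))
    cfg[[nm]] <- y[[nm]]
  for (pp in c("regression_params", "classification_params"))
    if (!is.null(y[[pp]]))
      for (nm in names(y[[pp]])) cfg[[pp]][[nm]] <- y[[pp]][[nm]]
  cfg
}

#' Run the full label-free cell-cycle pipeline on a synthetic population
#'
#' Stages: simulate (seeded) -> reshape to the standard tile -> segment
#' brightfield -> extract the 213-feature profile + ground-truth stain ->
#' k-fold cross-validated DNA-content regression and mitotic-phase
#' classification -> Watson pragmatic fit of the measured and the
#' out-of-fold predicted DNA-content histograms. Identical `(config, seed)`
#' give identical reports; when `out_dir` is set, artifacts (truth table,
#' feature CSV, QC CSV, report JSON) are written along with their MD5
#' lineage manifest.
#'
#' @param config a [run_config()].
#' @return named list report.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  pc <- population_config(n_cells = config$n_cells, seed = config$seed,
                          block_shift = config$block_shift)
  pop <- generate_population(pc)
  ft <- feature_table(pop, tile = config$tile, seed = config$seed)
  fm <- feature_matrix(ft$features)
  qc_counts <- table(factor(ft$qc$kept, c(FALSE, TRUE)))
  cv_dna <- cross_validate(fm$X, fm$meta$stain_integrated, k = config$k_folds,
                           task = "regression",
                           params = config$regression_params,
                           seed = config$seed)
  cv_phase <- cross_validate(fm$X, merge_phase_labels(fm$meta$phase),
                             k = config$k_folds,
                             task = "classification",
                             params = config$classification_params,
                             seed = config$seed)
  watson_measured <- fit_watson(build_histogram(fm$meta$stain_integrated,
                                                config$n_bins, "measured"))
  watson_predicted <- fit_watson(build_histogram(cv_dna$predictions,
                                                 config$n_bins, "predicted"))
  report <- list(
    n_cells = config$n_cells,
    seed = config$seed,
    manifest_version = ft$manifest_version,
    n_kept = sum(ft$qc$kept),
    n_discarded = sum(!ft$qc$kept),
    discard_reasons = table(ft$qc$reasons[!ft$qc$kept]),
    dna_cv = list(k = cv_dna$k, per_fold = cv_dna$per_fold,
                  mean = cv_dna$mean, sd = cv_dna$sd),
    phase_cv = list(k = cv_phase$k, mean = cv_phase$mean, sd = cv_phase$sd,
                    confusion = cv_phase$confusion),
    fractions_measured = watson_measured$fractions,
    fractions_predicted = watson_predicted$fractions
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      truth = file.path(config$out_dir, "truth.csv"),
      features = file.path(config$out_dir, "features.csv"),
      qc = file.path(config$out_dir, "qc.csv"),
      report = file.path(config$out_dir, "report.json"))
    write.csv(pop$truth, paths["truth"], row.names = FALSE)
    write_feature_table(ft$features, paths["features"])
    write.csv(ft$qc, paths["qc"], row.names = FALSE)
    jsonlite::write_json(report_to_json(report), paths["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    lineage <- data.frame(artifact = names(paths), path = unname(paths),
                          md5 = unname(tools::md5sum(paths)),
                          seed = config$seed)
    write.csv(lineage, file.path(config$out_dir, "lineage.csv"),
              row.names = FALSE)
    report$lineage <- lineage
  }
  report
}

report_to_json <- function(report) {
  rapply(report, function(x) {
    if (is.table(x)) as.list(setNames(as.numeric(x), names(x))) else x
  }, how = "replace")
}

#' Synthetic mitotic-block detection experiment
#'
#' The synthetic analogue of a Nocodazole block study: a stained untreated
#' population trains the DNA-content regressor; two further unstained
#' populations — an untreated control and a blocked one (`block_shift` of
#' the G1/S mass moved into the G2+mitotic pool) — are scored with the
#' trained model only, their predicted DNA-content histograms are Watson-
#' fitted, and the change in the G2/M fraction is reported. A phase
#' classifier with the blocked-protocol class grouping (interphase /
#' prophase / other mitotic) is cross-validated on the training arm.
#'
#' @param seed global seed.
#' @param n_train stained training cells.
#' @param n_test unstained cells per scored arm.
#' @param block_shift mass moved into the G2+mitotic pool (default 0.15).
#' @param regression_params,classification_params [boost_params()].
#' @param n_bins histogram bins.
#' @param run_classifier also cross-validate the merged-class phase
#'   classifier? (slower; default TRUE)
#' @param k_folds folds for the classifier CV.
#' @param model optional prefit `lsboost` DNA-content model; skips the
#'   training arm (useful for scoring several treatment arms with one
#'   trained regressor).
#' @return list with `fractions_control`, `fractions_blocked`, `delta`
#'   (named `G1`, `S`, `G2M`), the trained `model`, and `phase_cv` when
#'   the classifier runs.
#' @export
demo_block_experiment <- function(seed = 1L, n_train = 1500L, n_test = 1200L,
                                  block_shift = 0.15,
                                  regression_params = boost_params(M = 60L),
                                  classification_params = boost_params(M = 40L),
                                  n_bins = 64L, run_classifier = TRUE,
                                  k_folds = 10L, model = NULL) {
  fm_train <- NULL
  if (is.null(model)) {
    train_pop <- generate_population(
      population_config(n_cells = n_train, seed = seed))
    ft_train <- feature_table(train_pop, seed = seed)
    fm_train <- feature_matrix(ft_train$features)
    model <- fit_lsboost(fm_train$X, fm_train$meta$stain_integrated,
                         regression_params, seed = seed)
  }

  score_arm <- function(pop_seed, shift) {
    pop <- generate_population(
      population_config(n_cells = n_test, seed = pop_seed,
                        block_shift = shift),
      with_stain = FALSE)                       # unlabelled arm: no marker
    ft <- feature_table(pop, seed = pop_seed)
    fm <- feature_matrix(ft$features)
    predict(model, fm$X)
  }
  pred_control <- score_arm(seed + 1L, 0)
  pred_blocked <- score_arm(seed + 2L, block_shift)
  fit_control <- fit_watson(build_histogram(pred_control, n_bins, "predicted"))
  fit_blocked <- fit_watson(build_histogram(pred_blocked, n_bins, "predicted"))
  out <- list(
    seed = seed, block_shift = block_shift,
    fractions_control = fit_control$fractions,
    fractions_blocked = fit_blocked$fractions,
    delta = fit_blocked$fractions - fit_control$fractions,
    fit_control = fit_control, fit_blocked = fit_blocked,
    model = model,
    regression_train_mse = tail(model$train_loss, 1))
  if (run_classifier && !is.null(fm_train)) {
    merged <- merge_phase_labels(fm_train$meta$phase, "blocked")
    out$phase_cv <- cross_validate(fm_train$X, merged, k = k_folds,
                                   task = "classification",
                                   params = classification_params,
                                   seed = seed)
  }
  out
}
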
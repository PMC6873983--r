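#' Split a cohort into training and test sets
#'
#' Patient-level random split, reproducible from the seed. Unstratified,
#' the training set receives `round(fraction * n)` patients. With
#' `stratify` set to a grouping column, the split is drawn within each
#' stratum and the training side receives `ceiling(fraction * n_s)` of
#' each, so every stratum keeps at least its proportional share of
#' training patients: splitting the default three-cohort 1,186-patient
#' table 80/20 stratified by cohort gives 950 training and 236 test
#' patients, and the subsequent unstratified 80/20 split of those 950
#' gives 760 and 190.
#'
#' @param table cohort data frame.
#' @param fraction training fraction, strictly inside (0, 1).
#' @param seed RNG seed.
#' @param stratify optional name of a column to stratify on.
#' @return list with `train` and `test` data frames (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(table, fraction = 0.8, seed = 1L,
                         stratify = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  if (round(fraction * n) < 1) stop("training fraction selects no patients")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(stratify)) {
    idx <- sample.int(n, round(fraction * n))
  } else {
    g <- table[[stratify]]
    if (is.null(g)) stop("no column '", stratify, "' to stratify on")
    idx <- unlist(lapply(split(seq_len(n), g), function(rows) {
      sample(rows, min(length(rows), ceiling(fraction * length(rows))))
    }), use.names = FALSE)
  }
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Pipeline run configuration
#'
#' @param spec an `srn_cohort_spec` (used when no cohort CSV is given).
#' @param cohort_path optional path to an existing cohort CSV.
#' @param outer_fraction,inner_fraction train/test and bootstrap split
#'   fractions.
#' @param n_bootstrap bootstrap replicates (reference analysis: 100).
#' @param model_config an `srn_config`.
#' @param knn_k neighbours for imputation.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory; a timestamped run directory is
#'   created inside.
#' @return an object of class `srn_run_config`.
#' @export
run_config <- function(spec = gastric_cohort_spec(),
                       cohort_path = NULL,
                       outer_fraction = 0.8,
                       inner_fraction = 0.8,
                       n_bootstrap = 100L,
                       model_config = srn_config(),
                       knn_k = 5L,
                       seed = 1L,
                       out_dir = tempdir()) {
  stopifnot(outer_fraction > 0, outer_fraction < 1,
            inner_fraction > 0, inner_fraction < 1)
  structure(list(spec = spec, cohort_path = cohort_path,
                 outer_fraction = outer_fraction,
                 inner_fraction = inner_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 model_config = model_config, knn_k = as.integer(knn_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "srn_run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[srnet:%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Simulate (or load) the cohort, encode and impute, split into training
#' and test (stratified by cohort), run the bootstrap resampling study,
#' train the final model on the full training set with an internal
#' validation split, evaluate on the held-out test set, and run the
#' counterfactual treatment analysis. Every artifact -- resolved
#' configuration, cohort CSV, encoder parameters, model checkpoint,
#' per-year metrics, counterfactual grid, subgroup labels and
#' association tables -- is written under a timestamped run directory.
#'
#' @param config an `srn_run_config`.
#' @param quiet suppress progress messages.
#' @return list with the trained model, the evaluation report, the
#'   bootstrap summary, the counterfactual analysis, and `run_dir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "srn_run_config"))
  log <- if (quiet) function(...) invisible() else pipeline_log
  run_dir <- file.path(config$out_dir,
                       format(Sys.time(), "srn-run-%Y%m%d-%H%M%S"))
  i <- 1L
  while (dir.exists(run_dir)) {
    i <- i + 1L
    run_dir <- sub("(-[0-9]+)?$", paste0("-", i),
                   file.path(config$out_dir,
                             format(Sys.time(), "srn-run-%Y%m%d-%H%M%S")))
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  # stage: cohort
  cohort <- if (!is.null(config$cohort_path)) {
    log("load", "reading cohort from ", config$cohort_path)
    read_cohort(config$cohort_path)
  } else {
    log("simulate", "generating cohort n=", config$spec$n_total,
        " seed=", config$spec$seed)
    generate_cohort(config$spec)
  }
  write_cohort(cohort, file.path(run_dir, "cohort.csv"))

  # stage: split (outer, stratified by cohort when present)
  strat <- if ("cohort" %in% names(cohort)) "cohort"
  sp <- split_cohort(cohort, config$outer_fraction, seed = config$seed,
                     stratify = strat)
  log("split", "train n=", nrow(sp$train), ", test n=", nrow(sp$test))

  # stage: preprocess (fit on training rows only)
  schema <- config$spec$schema
  enc_tr <- encode_features(sp$train, schema = schema)
  enc_te <- encode_features(sp$test, encoder = enc_tr$encoder)
  x_tr <- enc_tr$x
  x_te <- enc_te$x
  if (anyNA(x_tr)) {
    x_tr <- round(knn_impute(x_tr, k = config$knn_k))
    storage.mode(x_tr) <- "integer"
  }
  if (anyNA(x_te)) {
    x_te <- round(knn_impute(x_te, k = config$knn_k, reference = x_tr))
    storage.mode(x_te) <- "integer"
  }
  write_encoder(enc_tr$encoder, file.path(run_dir, "encoder.json"))
  log("preprocess", ncol(x_tr), " encoded features; imputation k=",
      config$knn_k)

  train_data <- srn_data(x_tr, sp$train$survival_months, sp$train$event)
  test_data <- srn_data(x_te, sp$test$survival_months, sp$test$event)

  # stage: bootstrap study
  boot <- NULL
  if (config$n_bootstrap > 0) {
    log("bootstrap", config$n_bootstrap, " replicates")
    boot <- bootstrap_train(train_data, config$model_config,
                            n_replicates = config$n_bootstrap,
                            inner_split = config$inner_fraction)
    utils::write.csv(boot$summary,
                     file.path(run_dir, "bootstrap_auc.csv"),
                     row.names = FALSE)
  }

  # stage: final model (internal validation split for early stopping)
  inner <- split_cohort(data.frame(i = seq_len(nrow(x_tr))),
                        config$inner_fraction, seed = config$seed + 1L)
  fit_idx <- inner$train$i
  val_idx <- inner$test$i
  model <- init_srn(config$model_config, n_features = ncol(x_tr))
  log("train", "final model: fit n=", length(fit_idx), ", val n=",
      length(val_idx))
  model <- train_sequential(model,
                            subset_srn_data(train_data, fit_idx),
                            subset_srn_data(train_data, val_idx))
  model$encoder <- enc_tr$encoder
  save_srn(model, file.path(run_dir, "model.json"))
  utils::write.csv(model$history, file.path(run_dir, "history.csv"),
                   row.names = FALSE)

  # stage: evaluation on the held-out test set
  report <- evaluate_srn(model, test_data)
  log("evaluate", "test AUC ",
      paste(sprintf("%.3f", report$auc), collapse = "/"),
      "; c-index ", sprintf("%.3f", report$c_index))
  report_json <- list(
    auc_by_year = as.list(stats::setNames(report$auc, paste0("year", 1:5))),
    c_index = report$c_index,
    calibration_max_deviation = report$calibration$max_deviation,
    bootstrap_mean_auc = if (!is.null(boot)) as.list(
      stats::setNames(boot$summary$mean_auc, paste0("year", 1:5)))
  )
  jsonlite::write_json(report_json, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$calibration$bins,
                   file.path(run_dir, "calibration.csv"), row.names = FALSE)

  # stage: counterfactual treatment analysis
  grid <- counterfactual_predict(model, cohort, impute_reference = x_tr)
  subgroups <- assign_subgroups(grid)
  cf <- data.frame(patient_id = cohort$patient_id, grid$survival,
                   check.names = FALSE,
                   best_option = grid$best_option,
                   subgroup = subgroups)
  utils::write.csv(cf, file.path(run_dir, "counterfactual.csv"),
                   row.names = FALSE)
  assoc_factors <- intersect(
    c("molecular_subtype", "papillary", "perineural_invasion",
      "lymphovascular_invasion", "t_stage", "n_stage", "tumor_location",
      "lauren", "recurrence"), names(cohort))
  poor <- grid$survival[cbind(seq_len(nrow(cohort)),
                              match(cohort$treatment, grid$options))]
  poor[is.na(poor)] <- rowMeans(grid$survival)[is.na(poor)]
  assoc <- factor_association(cohort, poor < stats::median(poor),
                              assoc_factors)
  utils::write.csv(assoc, file.path(run_dir, "associations.csv"),
                   row.names = FALSE)
  log("recommend", "subgroups: ",
      paste(names(table(subgroups)), as.integer(table(subgroups)),
            sep = "=", collapse = ", "))

  # resolved configuration for reproducibility
  cfg_out <- list(seed = config$seed,
                  outer_fraction = config$outer_fraction,
                  inner_fraction = config$inner_fraction,
                  n_bootstrap = config$n_bootstrap,
                  knn_k = config$knn_k,
                  model_config = unclass(config$model_config),
                  cohort = list(n_total = config$spec$n_total,
                                seed = config$spec$seed))
  yaml::write_yaml(cfg_out, file.path(run_dir, "config.yaml"))

  list(model = model, report = report, bootstrap = boot,
       counterfactual = list(grid = grid, subgroups = subgroups,
                             associations = assoc),
       run_dir = run_dir)
}
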
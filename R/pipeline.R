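#' Pipeline configuration
#'
#' One configuration object drives the whole analysis: simulate -> extract ->
#' select -> fit -> evaluate -> report. Every stochastic stage derives its
#' seed from the single `master_seed`, and the configuration round-trips
#' losslessly through JSON ([save_pipeline_config()] /
#' [load_pipeline_config()]).
#'
#' @param output_dir where stage artifacts are written.
#' @param cohort a [cohort_config()]; its seed is re-derived from
#'   `master_seed`.
#' @param extraction an [extraction_config()].
#' @param alpha,rho_threshold,n_folds selection-cascade parameters.
#' @param split_ratio training fraction of the stratified split.
#' @param calibration_bins Hosmer-Lemeshow bin count.
#' @param master_seed single seed from which split/CV/cohort seeds derive.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            cohort = cohort_config(),
                            extraction = extraction_config(),
                            alpha = 0.05, rho_threshold = 0.9,
                            n_folds = 10L, split_ratio = 0.7,
                            calibration_bins = 10L,
                            master_seed = 1L) {
  cohort$seed <- .derive_seed(master_seed, 1L)
  structure(
    list(output_dir = output_dir, cohort = cohort, extraction = extraction,
         alpha = alpha, rho_threshold = rho_threshold,
         n_folds = as.integer(n_folds), split_ratio = split_ratio,
         calibration_bins = as.integer(calibration_bins),
         split_seed = .derive_seed(master_seed, 2L),
         cv_seed = .derive_seed(master_seed, 3L),
         master_seed = as.integer(master_seed)),
    class = "pipeline_config"
  )
}

#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @rdname pipeline_config
#' @export
save_pipeline_config <- function(config, path) {
  jsonlite::write_json(.config_as_list(config), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)  # 17 digits: lossless doubles
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON does not distinguish integer from double: restore the field types
  for (f in c("alpha", "rho_threshold", "split_ratio"))
    raw[[f]] <- as.numeric(raw[[f]])
  for (f in c("n_folds", "calibration_bins", "split_seed", "cv_seed", "master_seed"))
    raw[[f]] <- as.integer(raw[[f]])
  for (f in c("intensity_shift", "variance_ratio", "smoothness_ratio",
              "baseline_mean", "baseline_sd", "smooth_sigma"))
    raw$cohort[[f]] <- as.numeric(raw$cohort[[f]])
  for (f in c("n_che", "n_nche", "seed"))
    raw$cohort[[f]] <- as.integer(raw$cohort[[f]])
  raw$extraction <- lapply(raw$extraction, as.integer)
  raw$cohort$roi_shape <- as.integer(raw$cohort$roi_shape)
  for (cls in names(raw$cohort$clinical_params)) {
    cp <- lapply(raw$cohort$clinical_params[[cls]], unlist)
    for (v in c("nh3", "nct_a", "dst", "age", "education"))
      names(cp[[v]]) <- c("mean", "sd")
    names(cp$child_pugh_probs) <- c("A", "B", "C")
    raw$cohort$clinical_params[[cls]] <- cp
  }
  class(raw$cohort) <- "cohort_config"
  class(raw) <- "pipeline_config"
  raw
}

.stage_order <- c("simulate", "extract", "select", "fit", "evaluate", "report")

# strip S3 classes so the nested config serializes to plain JSON
.config_as_list <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out
}

.stage_artifact <- function(config, stage) {
  switch(stage,
    simulate = file.path(config$output_dir, "cohort", "clinical.csv"),
    extract = file.path(config$output_dir, "features.csv"),
    select = file.path(config$output_dir, "selection.json"),
    fit = file.path(config$output_dir, "model_card.json"),
    evaluate = file.path(config$output_dir, "calibration.csv"),
    report = file.path(config$output_dir, "report.json")
  )
}

.require_upstream <- function(config, stage) {
  i <- match(stage, .stage_order)
  if (i > 1L) {
    prev <- .stage_order[i - 1L]
    if (!file.exists(.stage_artifact(config, prev))) {
      stop("stage '", stage, "' needs the output of stage '", prev,
           "'; run run_stage(\"", prev, "\", config) first")
    }
  }
  invisible(TRUE)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run one pipeline stage
#'
#' Stages, in order: `simulate` (synthetic cohort on disk), `extract`
#' (feature table, 423 columns per ROI), `select` (stratified split +
#' three-stage cascade), `fit` (Radscore, R and R-C logistic models,
#' ROC/DeLong on both sets), `evaluate` (nomogram, calibration with
#' Hosmer-Lemeshow, Spearman correlations), `report` (concatenation of the
#' stage artifacts; no recomputation). Each stage writes its artifacts plus
#' a structured log line and fails with an explicit dependency error when
#' its upstream artifact is missing.
#'
#' @param stage one of `simulate`, `extract`, `select`, `fit`, `evaluate`,
#'   `report`.
#' @param config a [pipeline_config()].
#' @param verbose print per-subject extraction progress.
#' @return Invisibly, the stage's main in-memory artifact.
#' @export
run_stage <- function(stage, config, verbose = FALSE) {
  stage <- match.arg(stage, .stage_order)
  .require_upstream(config, stage)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(config$output_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  out <- switch(stage,
    simulate = {
      clin <- generate_cohort(config$cohort, file.path(config$output_dir, "cohort"))
      .log_stage(stage, nrow(clin), " subjects (",
                 sum(clin$group == "CHE"), " CHE / ",
                 sum(clin$group == "nCHE"), " nCHE), seed ", config$cohort$seed)
      clin
    },
    extract = {
      feat <- extract_cohort_features(file.path(config$output_dir, "cohort"),
                                      config$extraction, verbose = verbose)
      utils::write.csv(feat, file.path(config$output_dir, "features.csv"),
                       row.names = FALSE)
      .log_stage(stage, nrow(feat), " subjects x ", ncol(feat) - 2L, " features")
      feat
    },
    select = {
      feat <- utils::read.csv(file.path(config$output_dir, "features.csv"),
                              stringsAsFactors = FALSE, check.names = FALSE)
      split <- split_cohort(feat, ratio = config$split_ratio,
                            seed = config$split_seed)
      train <- feat[feat$subject_id %in% split$train_ids, ]
      sel <- select_features(train[, -(1:2)], train$group,
                             alpha = config$alpha,
                             rho_threshold = config$rho_threshold,
                             n_folds = config$n_folds, seed = config$cv_seed)
      jsonlite::write_json(
        list(counts = as.list(sel$counts),
             univariate_kept = sel$univariate$kept,
             excluded_degenerate = sel$univariate$excluded_degenerate,
             redundancy_kept = sel$redundancy_kept,
             selected = sel$selected_names,
             lambda_min = sel$lasso_fit$lambda_min,
             lambda_path = sel$lasso_fit$lambda_path,
             cv_mean = sel$lasso_fit$cv_mean,
             cv_se = sel$lasso_fit$cv_se,
             split = list(train_ids = split$train_ids,
                          test_ids = split$test_ids,
                          seed = split$seed)),
        file.path(config$output_dir, "selection.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .log_stage(stage, "cascade ", paste(sel$counts, collapse = " -> "),
                 " features; lambda_min = ", signif(sel$lasso_fit$lambda_min, 4))
      state$split <- split
      state$selection <- sel
      sel
    },
    fit = {
      feat <- utils::read.csv(file.path(config$output_dir, "features.csv"),
                              stringsAsFactors = FALSE, check.names = FALSE)
      clin <- utils::read.csv(file.path(config$output_dir, "cohort", "clinical.csv"),
                              stringsAsFactors = FALSE)
      split <- state$split
      sel <- state$selection
      if (is.null(split) || is.null(sel))
        stop("stage 'fit' needs the output of stage 'select'; ",
             "run run_stage(\"select\", config) first")
      models <- fit_models(feat, clin, split, sel)
      jsonlite::write_json(model_card(models),
                           file.path(config$output_dir, "model_card.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .log_stage(stage, "R testing AUC ", round(models$roc$R$test$auc, 3),
                 "; R-C testing AUC ", round(models$roc$`R-C`$test$auc, 3))
      state$models <- models
      models
    },
    evaluate = {
      models <- state$models
      if (is.null(models))
        stop("stage 'evaluate' needs the output of stage 'fit'; ",
             "run run_stage(\"fit\", config) first")
      ev <- evaluate_models(models, calibration_bins = config$calibration_bins)
      utils::write.csv(ev$calibration_table,
                       file.path(config$output_dir, "calibration.csv"),
                       row.names = FALSE)
      utils::write.csv(ev$correlation_table,
                       file.path(config$output_dir, "correlations.csv"),
                       row.names = FALSE)
      jsonlite::write_json(ev$nomogram_table,
                           file.path(config$output_dir, "nomogram.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .log_stage(stage, "HL p (train) = ", round(ev$hl$train$hl_p, 3),
                 "; HL p (test) = ", round(ev$hl$test$hl_p, 3))
      state$evaluation <- ev
      ev
    },
    report = {
      paths <- list(
        selection = file.path(config$output_dir, "selection.json"),
        model_card = file.path(config$output_dir, "model_card.json"),
        nomogram = file.path(config$output_dir, "nomogram.json")
      )
      report <- lapply(paths, function(p) jsonlite::read_json(p, simplifyVector = TRUE))
      report$calibration <- utils::read.csv(file.path(config$output_dir, "calibration.csv"))
      report$correlations <- utils::read.csv(file.path(config$output_dir, "correlations.csv"))
      report$config <- .config_as_list(config)
      jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .log_stage(stage, "written to ", file.path(config$output_dir, "report.json"))
      report
    }
  )
  saveRDS(state, state_path)
  invisible(out)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  for (stage in .stage_order) run_stage(stage, config, verbose = verbose)
  invisible(jsonlite::read_json(file.path(config$output_dir, "report.json"),
                                simplifyVector = TRUE))
}

#' Fit and evaluate the R and R-C models on a split cohort
#'
#' The modeling half of the pipeline as one call: Radscore from the LASSO
#' fit, unpenalized logistic refits, ROC with training-derived Youden
#' threshold applied unchanged to the testing set, and the paired DeLong
#' comparison of the two models on each set.
#'
#' @param feat feature table (`subject_id`, `group`, features).
#' @param clin clinical table.
#' @param split a `split_assignment`.
#' @param sel a `selection_report`.
#' @return A `models_bundle` list.
#' @export
fit_models <- function(feat, clin, split, sel) {
  sig <- radscore_model(sel$lasso_fit)
  idx_tr <- feat$subject_id %in% split$train_ids
  tr_f <- feat[idx_tr, ]; te_f <- feat[!idx_tr, ]
  tr_c <- clin[match(tr_f$subject_id, clin$subject_id), ]
  te_c <- clin[match(te_f$subject_id, clin$subject_id), ]
  r <- fit_r_model(tr_f, tr_f$group, sig)
  rc <- fit_rc_model(tr_f, tr_c, tr_f$group, sig)
  probs <- list(
    R = list(train = predict_prob(r, tr_f), test = predict_prob(r, te_f)),
    `R-C` = list(train = predict_prob(rc, tr_f, tr_c),
                 test = predict_prob(rc, te_f, te_c))
  )
  roc <- lapply(probs, function(pr) {
    tr_roc <- roc_analysis(pr$train, tr_f$group, operating = "youden")
    te_roc <- roc_analysis(pr$test, te_f$group, operating = "fixed",
                           threshold = tr_roc$operating_threshold)
    list(train = tr_roc, test = te_roc)
  })
  delong <- list(
    train = delong_test(probs$R$train, probs$`R-C`$train,
                        as.numeric(tr_f$group == "CHE")),
    test = delong_test(probs$R$test, probs$`R-C`$test,
                       as.numeric(te_f$group == "CHE"))
  )
  structure(
    list(signature = sig, r_model = r, rc_model = rc, probs = probs,
         roc = roc, delong = delong,
         train = list(features = tr_f, clinical = tr_c),
         test = list(features = te_f, clinical = te_c)),
    class = "models_bundle"
  )
}

#' Machine-readable twin of the performance table
#'
#' @param models a [fit_models()] bundle.
#' @return Nested list: per model and set, AUC with 95% CI, ACC/SEN/SPE and
#'   the operating threshold, plus the DeLong train/test p-values and the
#'   Radscore coefficients.
#' @export
model_card <- function(models) {
  per_set <- function(rr) list(
    auc = rr$auc, auc_ci_95 = rr$auc_ci_95, acc = rr$acc, sen = rr$sen,
    spe = rr$spe, threshold = rr$operating_threshold
  )
  list(
    radscore = list(beta0 = models$signature$beta0,
                    coefficients = as.list(models$signature$betas)),
    R = list(train = per_set(models$roc$R$train),
             test = per_set(models$roc$R$test),
             coefficients = as.list(models$r_model$coefficients)),
    `R-C` = list(train = per_set(models$roc$`R-C`$train),
                 test = per_set(models$roc$`R-C`$test),
                 coefficients = as.list(models$rc_model$coefficients)),
    delong_p = list(train = models$delong$train$p_value,
                    test = models$delong$test$p_value)
  )
}

#' Nomogram, calibration and correlation outputs for a fitted bundle
#'
#' @param models a [fit_models()] bundle.
#' @param calibration_bins Hosmer-Lemeshow bin count.
#' @return List with the nomogram object and table, per-set calibration
#'   results (`hl`), a long calibration table, and the Spearman correlation
#'   table.
#' @export
evaluate_models <- function(models, calibration_bins = 10L) {
  tr <- models$train; te <- models$test
  nomo_data <- data.frame(
    radscore = radscore(models$signature, tr$features),
    nh3 = tr$clinical$nh3,
    child_pugh = child_pugh_ordinal(tr$clinical$child_pugh)
  )
  nomo <- build_nomogram(models$rc_model, nomo_data)
  hl <- list(
    train = calibration(models$probs$`R-C`$train,
                        as.numeric(tr$features$group == "CHE"),
                        g = min(calibration_bins, nrow(tr$features))),
    test = calibration(models$probs$`R-C`$test,
                       as.numeric(te$features$group == "CHE"),
                       g = min(calibration_bins, nrow(te$features)))
  )
  cal_tab <- do.call(rbind, lapply(names(hl), function(s) {
    b <- hl[[s]]$bins
    data.frame(set = s, bin = seq_len(nrow(b)), b,
               hl_chi2 = hl[[s]]$hl_chi2, hl_df = hl[[s]]$hl_df,
               hl_p = hl[[s]]$hl_p)
  }))
  all_feat <- rbind(tr$features, te$features)
  all_clin <- rbind(tr$clinical, te$clinical)
  corr <- correlation_report(all_feat, all_clin, signature = models$signature)
  corr_tab <- data.frame(
    feature = rep(rownames(corr$rho), times = ncol(corr$rho)),
    clinical = rep(colnames(corr$rho), each = nrow(corr$rho)),
    rho = as.vector(corr$rho), p = as.vector(corr$p)
  )
  list(
    nomogram = nomo,
    nomogram_table = do.call(rbind, nomo$axes),
    hl = hl, calibration_table = cal_tab,
    correlation = corr, correlation_table = corr_tab
  )
}
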
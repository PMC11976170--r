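# End-to-end orchestration: configuration validation with defaults and
# provenance, and a single reproducible experiment runner covering
# simulate -> preselect -> represent -> split -> train -> evaluate -> explain.

default_run_config <- function() {
  list(seed = 1L,
       cohort = NULL,            # list of cohort_config() overrides
       cohort_dir = NULL,        # alternatively: a written cohort directory
       n_test_patients = 60L,    # size of the shifted-center test cohort
       models = c("rf_feature", "rf_time", "cnn1d", "cnn2d"),
       fraction_train = 0.7,
       thresholds = seq(0.25, 0.9, by = 0.05),
       explain = TRUE,
       explain_sample = 300L,    # traces per CNN for averaged Grad-CAMs
       cnn1d = list(epochs = 30L, batch = 64L, lr = 1e-3, patience = 5L),
       cnn2d = list(epochs = 10L, batch = 64L, lr = 1e-3, patience = 4L),
       out_dir = NULL,
       verbose = FALSE)
}

#' Validate and normalise a run configuration
#'
#' Fills defaults, checks keys strictly (unknown or conflicting keys are
#' errors), materialises per-stage seeds from the master seed, and attaches a
#' provenance record. Normalisation is idempotent.
#'
#' @param config A named list of overrides, a path to a YAML file, or `NULL`
#'   for the full default configuration.
#' @return List with `config` (normalised) and `provenance` (package version,
#'   R version, stage seeds).
#' @export
validate_and_log <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  if (!is.list(config)) abort_param("config must be a list or YAML path")
  defaults <- default_run_config()
  known <- c(names(defaults), "stage_seeds")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort_param(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$cohort) && !is.null(config$cohort_dir)) {
    abort_param("conflicting keys: 'cohort' and 'cohort_dir' are exclusive")
  }
  cfg <- defaults
  # single-bracket assignment so NULL-valued keys are kept, not deleted;
  # CNN sublists merge key-wise so partial overrides keep the other defaults
  for (nm in names(config)) {
    if (nm %in% c("cnn1d", "cnn2d") && is.list(config[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    } else {
      cfg[nm] <- config[nm]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$models,
                 c("rf_feature", "rf_time", "cnn1d", "cnn2d"))
  if (length(bad) > 0) {
    abort_param(paste("unknown model(s):", paste(bad, collapse = ", ")))
  }
  cfg$stage_seeds <- list(cohort = cfg$seed,
                          cohort_test = cfg$seed + 1L,
                          split = cfg$seed + 2L,
                          rf_feature = cfg$seed + 3L,
                          rf_time = cfg$seed + 4L,
                          cnn1d = cfg$seed + 5L,
                          cnn2d = cfg$seed + 6L,
                          shap = cfg$seed + 7L,
                          explain = cfg$seed + 8L)
  provenance <- list(package = "mepmuscle",
                     version = as.character(utils::packageVersion("mepmuscle")),
                     r_version = R.version.string,
                     stage_seeds = cfg$stage_seeds)
  list(config = cfg, provenance = provenance)
}

stage_msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full classification experiment
#'
#' Generates (or loads) a training/validation cohort and a shifted-center
#' test cohort, applies preselection, builds the representations each
#' requested model needs, trains with a patient-stratified 70/30 split and
#' class weighting, and evaluates validation accuracy, shifted-center test
#' accuracy, confusion matrices, confidence curves and per-muscle dispersion.
#' Optionally adds the explainability layer (impurity importances, Shapley
#' attributions and directionality for the feature forest; averaged Grad-CAMs
#' for the CNNs).
#'
#' @param config Overrides accepted by [validate_and_log].
#' @return A list of class `run_report`.
#' @export
run_experiment <- function(config = NULL) {
  vc <- validate_and_log(config)
  cfg <- vc$config
  seeds <- cfg$stage_seeds
  vb <- isTRUE(cfg$verbose)

  stage_msg(vb, "stage simulate: generating cohorts")
  if (!is.null(cfg$cohort_dir)) {
    cohort <- read_cohort(cfg$cohort_dir)
    cohort_cfg <- NULL
  } else {
    cohort_args <- cfg$cohort %||% list()
    cohort_cfg <- do.call(cohort_config,
                          utils::modifyList(cohort_args,
                                            list(center = "T1",
                                                 seed = seeds$cohort)))
    cohort <- generate_cohort(cohort_cfg)
  }
  test_args <- cfg$cohort %||% list()
  test_cfg <- do.call(cohort_config,
                      utils::modifyList(test_args,
                                        list(center = "T2",
                                             n_patients = cfg$n_test_patients,
                                             seed = seeds$cohort_test)))
  test_cohort <- generate_cohort(test_cfg)

  stage_msg(vb, "stage preselect")
  sel <- preselect(cohort)
  sel_test <- preselect(test_cohort)
  keep <- sel$is_mep & !is.na(cohort$meta$muscle)
  keep_test <- sel_test$is_mep & !is.na(test_cohort$meta$muscle)
  log <- list(n_generated = nrow(cohort$signals),
              n_rejected = sum(!sel$is_mep),
              n_accepted_labeled = sum(keep),
              n_test_generated = nrow(test_cohort$signals),
              n_test_accepted_labeled = sum(keep_test))

  stage_msg(vb, "stage represent")
  timerep <- time_representation(cohort, keep)
  timerep_test <- time_representation(test_cohort, keep_test)
  featrep <- feature_representation(timerep)
  featrep_test <- feature_representation(timerep_test)

  stage_msg(vb, "stage split")
  split <- patient_stratified_split(timerep$meta, cfg$fraction_train,
                                    seed = seeds$split)
  tr_rows <- timerep$meta$patient_id %in% split$train_patient_ids
  stopifnot(!any(timerep$meta$patient_id[tr_rows] %in%
                   split$validation_patient_ids))
  weights <- compute_class_weights(timerep$meta$muscle[tr_rows])

  needs_scalo <- "cnn2d" %in% cfg$models
  scalo <- scalo_test <- NULL
  if (needs_scalo) {
    stage_msg(vb, "stage represent: scalograms")
    scalo <- scalogram_stack(timerep$values, pool = 8L)
    scalo_test <- scalogram_stack(timerep_test$values, pool = 8L)
  }

  models <- list()
  evaluation <- list()
  for (fam in cfg$models) {
    stage_msg(vb, "stage train: %s", fam)
    pid_tr <- timerep$meta$patient_id[tr_rows]
    y_tr <- timerep$meta$muscle[tr_rows]
    model <- switch(fam,
      rf_feature = {
        ftr <- featrep$meta$patient_id %in% split$train_patient_ids
        train_random_forest(featrep$values[ftr, , drop = FALSE],
                            featrep$meta$muscle[ftr], weights,
                            seed = seeds$rf_feature,
                            patient_ids = featrep$meta$patient_id[ftr])
      },
      rf_time = train_random_forest(timerep$values[tr_rows, , drop = FALSE],
                                    y_tr, weights, seed = seeds$rf_time,
                                    patient_ids = pid_tr),
      cnn1d = train_cnn1d(timerep$values[tr_rows, , drop = FALSE], y_tr,
                          weights, seed = seeds$cnn1d, patient_ids = pid_tr,
                          epochs = cfg$cnn1d$epochs, batch = cfg$cnn1d$batch,
                          lr = cfg$cnn1d$lr, patience = cfg$cnn1d$patience,
                          verbose = vb),
      cnn2d = train_cnn2d(slice_obs(scalo, which(tr_rows)), y_tr, weights,
                          seed = seeds$cnn2d, patient_ids = pid_tr,
                          epochs = cfg$cnn2d$epochs, batch = cfg$cnn2d$batch,
                          lr = cfg$cnn2d$lr, patience = cfg$cnn2d$patience,
                          verbose = vb))
    models[[fam]] <- model

    val_rows <- !tr_rows
    if (fam == "rf_feature") {
      Xval <- featrep$values[featrep$meta$patient_id %in%
                               split$validation_patient_ids, , drop = FALSE]
      yval <- featrep$meta$muscle[featrep$meta$patient_id %in%
                                    split$validation_patient_ids]
      Xtest <- featrep_test$values
      ytest <- featrep_test$meta$muscle
    } else if (fam == "cnn2d") {
      Xval <- slice_obs(scalo, which(val_rows))
      yval <- timerep$meta$muscle[val_rows]
      Xtest <- scalo_test
      ytest <- timerep_test$meta$muscle
    } else {
      Xval <- timerep$values[val_rows, , drop = FALSE]
      yval <- timerep$meta$muscle[val_rows]
      Xtest <- timerep_test$values
      ytest <- timerep_test$meta$muscle
    }
    pv <- predict_proba(model, Xval)
    pt <- predict_proba(model, Xtest)
    pred_v <- classify_with_threshold(pv)
    pred_t <- classify_with_threshold(pt)
    per_class <- vapply(MUSCLES, function(m) {
      sel <- yval == m
      if (!any(sel)) return(NA_real_)
      accuracy(pred_v[sel], yval[sel])
    }, numeric(1))
    evaluation[[fam]] <- list(
      validation_accuracy = accuracy(pred_v, yval),
      test_accuracy = accuracy(pred_t, ytest),
      confusion_validation = confusion_matrix(pred_v, yval),
      confusion_test = confusion_matrix(pred_t, ytest),
      confidence_curve = confidence_curve(pt, ytest,
                                          thresholds = cfg$thresholds),
      per_class_validation = per_class,
      dispersion = performance_dispersion(per_class))
  }

  xai <- NULL
  if (isTRUE(cfg$explain)) {
    stage_msg(vb, "stage explain")
    xai <- list()
    if (!is.null(models$rf_feature)) {
      report <- shap_attributions(models$rf_feature, seed = seeds$shap)
      xai$rf_feature <- list(
        impurity = impurity_importance(models$rf_feature),
        shap_global = report$global_importance,
        shap_base_values = report$base_values,
        shap_direction = shap_direction_summary(report))
    }
    for (fam in intersect(c("cnn1d", "cnn2d"), names(models))) {
      rows <- which(tr_rows)
      rows <- with_seed(seeds$explain,
                        sample(rows, min(cfg$explain_sample, length(rows))))
      maps <- vector("list", length(rows))
      for (i in seq_along(rows)) {
        input <- if (fam == "cnn1d") timerep$values[rows[i], ] else
          scalo[rows[i], , ]
        maps[[i]] <- gradcam(models[[fam]], input,
                             as.character(timerep$meta$muscle[rows[i]]))
      }
      xai[[fam]] <- list(
        overall = average_gradcams(maps)$overall,
        per_muscle = average_gradcams(
          maps, by = as.character(timerep$meta$muscle[rows])))
    }
  }

  report <- structure(list(config = cfg, provenance = vc$provenance,
                           log = log, split = split,
                           class_weights = weights,
                           models = models, evaluation = evaluation,
                           xai = xai),
                      class = "run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  accepted labeled recordings: %d (train+validation), %d (test)\n",
              x$log$n_accepted_labeled, x$log$n_test_accepted_labeled))
  for (fam in names(x$evaluation)) {
    e <- x$evaluation[[fam]]
    cat(sprintf("  %-10s validation %.3f | shifted-center test %.3f\n",
                fam, e$validation_accuracy, e$test_accuracy))
  }
  invisible(x)
}

# JSON + CSV artifacts of a run; every number is recomputable from the
# serialized config and seeds.
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- list(config = report$config[setdiff(names(report$config),
                                                 c("out_dir"))],
                  provenance = report$provenance,
                  log = report$log,
                  class_weights = as.list(report$class_weights),
                  evaluation = lapply(report$evaluation, function(e) {
                    list(validation_accuracy = e$validation_accuracy,
                         test_accuracy = e$test_accuracy,
                         per_class_validation = as.list(e$per_class_validation),
                         dispersion = as.list(e$dispersion))
                  }))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (fam in names(report$evaluation)) {
    e <- report$evaluation[[fam]]
    utils::write.csv(e$confidence_curve,
                     file.path(dir, paste0("confidence_", fam, ".csv")),
                     row.names = FALSE)
    utils::write.csv(e$confusion_test$counts,
                     file.path(dir, paste0("confusion_test_", fam, ".csv")))
  }
  invisible(dir)
}
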
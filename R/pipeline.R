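#' Run the full analysis on a cohort
#'
#' Executes the analysis stages downstream of data generation on one cohort:
#' connectome construction, holdout reservation, autoencoder fitting on the
#' non-holdout subjects (so no held-out subject influences any training
#' statistic), sparse-unit pruning, feature assembly, nested stratified
#' cross-validation, evaluation, permutation importance with network-level
#' attribution and voxel projection, and survival reporting (Kaplan-Meier +
#' log-rank over the model-predicted cross-validation groups, plus cohort
#' group tests).
#'
#' @param cohort A `gbm_cohort` with time series (or `connectomes` supplied).
#' @param maps Optional probability maps for the voxel projection.
#' @param connectomes Optional precomputed connectome matrix.
#' @param classifier A [classifier_config()].
#' @param encoder List of overrides for [fit_autoencoder()] /
#'   [prune_sparse_features()] (`hidden_dim`, `lr`, `max_epochs`, `patience`,
#'   `tol_rel`, ...).
#' @param importance_repeats Permutation repeats (default 100); set to 0 to
#'   skip the importance stage.
#' @param within_method Within-network similarity reading (see
#'   [within_network_similarity()]).
#' @param seed Master seed for holdout choice, encoder and classifier.
#' @return List of class `gbm_experiment` with elements `connectomes`,
#'   `encoder`, `features`, `labels`, `ensemble`, `report`, `importance`,
#'   `km`, `logrank`, `group_tests`, `holdout_ids`.
#' @export
run_experiment <- function(cohort, maps = NULL, connectomes = NULL,
                           classifier = classifier_config(),
                           encoder = list(), importance_repeats = 100,
                           within_method = c("set", "pairwise"), seed = 1) {
  within_method <- match.arg(within_method)
  seeds <- derive_seeds(seed, 4L)
  if (is.null(connectomes)) {
    connectomes <- build_connectome_table(cohort,
                                          within_method = within_method)
  }
  subj <- cohort$subjects
  labels_all <- factor(subj$survival_class, levels = survival_classes())

  hold_idx <- if (classifier$holdout > 0) {
    stratified_sample(labels_all, classifier$holdout, seeds[1L])
  } else integer(0)
  holdout_ids <- subj$subject_id[hold_idx]
  train_ids <- setdiff(subj$subject_id, holdout_ids)

  enc_args <- utils::modifyList(
    list(hidden_dim = 20, val_fraction = 0.2, lr = 2, momentum = 0.9,
         max_epochs = 5000, patience = 100, tol_rel = 1e-4),
    encoder)
  tol_rel <- enc_args$tol_rel
  enc_args$tol_rel <- NULL
  enc_args$connectomes <- connectomes[train_ids, , drop = FALSE]
  enc_args$seed <- seeds[2L]
  model <- do.call(fit_autoencoder, enc_args)
  model <- prune_sparse_features(model, connectomes[train_ids, , drop = FALSE],
                                 tol_rel = tol_rel)

  fx <- assemble_features(cohort, connectomes, model)
  ensemble <- train_nested_cv(fx$features, fx$labels, config = classifier,
                              seed = seeds[3L], holdout_ids = holdout_ids)
  report <- evaluate_ensemble(ensemble, fx$features, fx$labels)

  imp <- NULL
  if (importance_repeats > 0) {
    imp <- importance_report(ensemble, fx$features, fx$labels, model,
                             repeats = importance_repeats, seed = seeds[4L],
                             maps = maps)
  }

  cvp <- ensemble$cv_predictions
  surv_tab <- data.frame(
    time = subj$survival_months[match(cvp$subject_id, subj$subject_id)],
    event = subj$event[match(cvp$subject_id, subj$subject_id)],
    group = cvp$pred, stringsAsFactors = FALSE)
  km <- km_estimate(surv_tab)
  lr_test <- if (length(unique(surv_tab$group)) >= 2L) {
    logrank_test(surv_tab)
  }
  gtests <- group_tests(subj)

  structure(list(connectomes = connectomes, encoder = model,
                 features = fx$features, labels = fx$labels,
                 ensemble = ensemble, report = report, importance = imp,
                 km = km, logrank = lr_test, group_tests = gtests,
                 holdout_ids = holdout_ids, seed = as.integer(seed)),
            class = "gbm_experiment")
}

#' @export
print.gbm_experiment <- function(x, ...) {
  cat("GBM survival-classification experiment\n")
  cat(" subjects:", nrow(x$features), " features:", ncol(x$features),
      " encoded FC:", length(x$encoder$kept_features), "\n")
  print(x$report)
  if (!is.null(x$logrank)) {
    cat(sprintf("Log-rank (predicted CV groups): chi2 = %.2f, df = %d, p = %.3g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  }
  invisible(x)
}

default_run_config <- function() {
  list(
    sim = list(),            # overrides for sim_config()
    encoder = list(),        # overrides for fit_autoencoder()/pruning
    classifier = list(),     # overrides for classifier_config()
    importance = list(repeats = 100),
    within_method = "set",
    write_timeseries = FALSE,
    probability_maps = TRUE
  )
}

#' Run the end-to-end pipeline and write its artifacts
#'
#' Orchestrates simulate -> connectome -> encode -> train -> importance ->
#' report from a single configuration, writing every artifact under
#' `out_dir` and returning a manifest with MD5 checksums; an identical
#' configuration and seed reproduce identical checksums.  The configuration
#' is a nested list (or the path of a YAML file with the same structure)
#' with sections `sim`, `encoder`, `classifier`, `importance`, plus
#' `within_method`, `write_timeseries` and `probability_maps`; every stage
#' seed is derived from `seed`.
#'
#' @param config Nested configuration list or YAML file path; omitted
#'   sections fall back to stage defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed.
#' @return List of class `gbm_run`: `experiment`, `manifest` (data frame
#'   `stage`, `file`, `md5`), `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gbmsurv_run"),
                         seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 2L)
  manifest <- list()
  note <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  # simulate
  sim_args <- cfg$sim
  sim_args$seed <- seeds[1L]
  scfg <- do.call(sim_config, sim_args)
  cohort <- generate_cohort(scfg)
  f <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, f); note("simulate", f)
  if (isTRUE(cfg$write_timeseries)) {
    ts_dir <- file.path(out_dir, "timeseries")
    dir.create(ts_dir, showWarnings = FALSE)
    for (id in names(cohort$timeseries)) {
      tf <- file.path(ts_dir, paste0(id, ".tsv"))
      write_timeseries(cohort$timeseries[[id]], tf)
      note("simulate", tf)
    }
  }
  maps <- NULL
  if (isTRUE(cfg$probability_maps)) {
    maps <- generate_probability_maps(scfg)
    f <- file.path(out_dir, "probability_maps.csv")
    write_probability_maps(maps, f); note("simulate", f)
  }

  repeats <- if (!is.null(cfg$importance$repeats)) cfg$importance$repeats else 100
  classifier <- do.call(classifier_config, cfg$classifier)
  exp <- run_experiment(cohort, maps = maps, classifier = classifier,
                        encoder = cfg$encoder,
                        importance_repeats = repeats,
                        within_method = cfg$within_method, seed = seeds[2L])

  f <- file.path(out_dir, "connectomes.csv")
  write_connectomes_csv(exp$connectomes, f); note("connectome", f)

  feats <- data.frame(subject_id = rownames(exp$features), exp$features,
                      check.names = FALSE, stringsAsFactors = FALSE)
  f <- file.path(out_dir, "features.csv")
  write.csv(feats, f, row.names = FALSE); note("encode", f)

  cvp <- exp$ensemble$cv_predictions
  av <- predict(exp$ensemble, exp$features, mode = "averaged")
  preds <- data.frame(
    subject_id = rownames(exp$features),
    true = as.character(exp$labels),
    averaged_pred = as.character(av$labels),
    holdout = rownames(exp$features) %in% exp$holdout_ids,
    cv_pred = cvp$pred[match(rownames(exp$features), cvp$subject_id)],
    av$scores, check.names = FALSE, stringsAsFactors = FALSE)
  f <- file.path(out_dir, "predictions.csv")
  write.csv(preds, f, row.names = FALSE); note("train", f)

  rep <- exp$report
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    cv_accuracy = rep$cv_accuracy,
    holdout_accuracy = rep$holdout_accuracy,
    holdout_accuracy_per_model_mean = rep$holdout_accuracy_per_model_mean,
    combined_accuracy = rep$combined_accuracy,
    ensemble_accuracy = rep$ensemble_accuracy,
    n_cv = rep$n_cv, n_holdout = rep$n_holdout,
    encoded_features_kept = length(exp$encoder$kept_features)
  ), f, auto_unbox = TRUE, digits = NA)
  note("train", f)

  if (!is.null(exp$importance)) {
    imp <- exp$importance
    sec <- rbind(
      data.frame(section = "per_feature", name = imp$per_feature$feature,
                 value = imp$per_feature$importance,
                 stringsAsFactors = FALSE),
      data.frame(section = "per_fc_pair", name = names(imp$per_fc_pair),
                 value = unname(imp$per_fc_pair), stringsAsFactors = FALSE),
      data.frame(section = "per_network", name = imp$per_network$network,
                 value = imp$per_network$mean, stringsAsFactors = FALSE))
    f <- file.path(out_dir, "importance.csv")
    write.csv(sec, f, row.names = FALSE); note("importance", f)
    if (!is.null(imp$voxel_map)) {
      f <- file.path(out_dir, "voxel_map.csv")
      write.csv(data.frame(voxel = seq_along(imp$voxel_map),
                           value = imp$voxel_map), f, row.names = FALSE)
      note("importance", f)
    }
  }

  f <- file.path(out_dir, "km_curves.csv")
  write.csv(exp$km, f, row.names = FALSE); note("report", f)
  f <- file.path(out_dir, "tests.csv")
  write.csv(exp$group_tests, f, row.names = FALSE); note("report", f)

  structure(list(experiment = exp,
                 manifest = do.call(rbind, manifest),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "gbm_run")
}
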
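test_that("feature assembly joins demographics, CT and encoded FC by id", {
  cfg <- tiny_sim_config(n_subjects = 12, seed = 3)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  set.seed(4)
  conn <- matrix(runif(12 * 120), 12, 120,
                 dimnames = list(coh$subjects$subject_id, fc_pair_labels()))
  enc <- make_toy_encoder(kept = 1:11)
  fx <- assemble_features(coh, conn, enc)
  expect_equal(dim(fx$features), c(12, 2 + 34 + 11))
  expect_equal(colnames(fx$features)[1:2], c("age", "sex"))
  expect_equal(colnames(fx$features)[37:47], paste0("FC", 1:11))
  expect_equal(rownames(fx$features), coh$subjects$subject_id)

  # shuffled connectome rows: identical output (id-keyed join)
  fx2 <- assemble_features(coh, conn[sample(12), ], enc)
  expect_equal(fx2$features, fx$features)

  # missing subject is reported by id
  expect_error(assemble_features(coh, conn[-3, , drop = FALSE], enc),
               coh$subjects$subject_id[3])

  # empty cohort is a vacuous join
  coh0 <- generate_cohort(tiny_sim_config(n_subjects = 0), timeseries = FALSE)
  fx0 <- assemble_features(coh0, conn, enc)
  expect_equal(nrow(fx0$features), 0)
})

test_that("nested CV is perfect on widely separable classes", {
  sep <- make_separable_features(n_per_class = 20, seed = 2)
  cfg <- classifier_config(outer_folds = 5, inner_folds = 2, holdout = 6,
                           max_epochs = 150, patience = 20)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 7)
  rep <- evaluate_ensemble(ens, sep$features, sep$labels)
  expect_equal(rep$cv_accuracy, 1)
  expect_equal(rep$ensemble_accuracy, 1)
  expect_equal(rep$combined_accuracy, 1)
  expect_equal(rep$holdout_accuracy, 1)
})

test_that("nested CV bookkeeping: stratification, leakage, determinism", {
  sep <- make_separable_features(n_per_class = 18, gap = 2, seed = 5)
  cfg <- classifier_config(outer_folds = 4, inner_folds = 1, holdout = 6,
                           max_epochs = 80, patience = 15)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 11)

  # each non-holdout subject has exactly one out-of-fold prediction
  rest <- setdiff(rownames(sep$features), ens$holdout_ids)
  expect_setequal(ens$cv_predictions$subject_id, rest)
  expect_equal(anyDuplicated(ens$cv_predictions$subject_id), 0)
  # holdout disjoint from CV subjects
  expect_length(intersect(ens$holdout_ids, ens$cv_predictions$subject_id), 0)
  # holdout stratified: 2 per class
  hl <- sep$labels[match(ens$holdout_ids, rownames(sep$features))]
  expect_equal(as.integer(table(hl)), c(2, 2, 2))
  # outer folds stratified within one subject of equal proportions
  tab <- table(ens$cv_predictions$fold,
               sep$labels[match(ens$cv_predictions$subject_id,
                                rownames(sep$features))])
  expect_lte(max(tab) - min(tab), 1)

  ens2 <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 11)
  expect_identical(ens$cv_predictions, ens2$cv_predictions)
  expect_identical(ens$members[[1]]$params, ens2$members[[1]]$params)

  # too-small cohorts are rejected
  expect_error(train_nested_cv(sep$features[1:2, ], sep$labels[1:2],
                               config = cfg, seed = 1),
               "stratification error")
})

test_that("prediction modes agree where they must", {
  sep <- make_separable_features(n_per_class = 15, seed = 8)
  cfg <- classifier_config(outer_folds = 3, inner_folds = 1, holdout = 0,
                           max_epochs = 60, patience = 10)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 3)

  # single-member ensemble: averaged equals that member
  solo <- ens
  solo$members <- ens$members[1]
  av <- predict(solo, sep$features, mode = "averaged")
  pm <- predict(solo, sep$features, mode = "per-model")
  expect_equal(as.character(av$labels), unname(pm$labels[, 1]))

  # unanimous members force the averaged label
  pm_all <- predict(ens, sep$features, mode = "per-model")
  unanimous <- apply(pm_all$labels, 1, function(r) length(unique(r)) == 1)
  av_all <- predict(ens, sep$features, mode = "averaged")
  expect_equal(as.character(av_all$labels)[unanimous],
               unname(pm_all$labels[unanimous, 1]))

  expect_error(predict(ens, sep$features[, 1:2]), "shape error")
})

test_that("accuracy report arithmetic follows its definition", {
  sep <- make_separable_features(n_per_class = 15, gap = 0.3, seed = 12)
  cfg <- classifier_config(outer_folds = 3, inner_folds = 1, holdout = 6,
                           max_epochs = 60, patience = 10)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 4)
  rep <- evaluate_ensemble(ens, sep$features, sep$labels)
  cv_correct <- sum(ens$cv_predictions$pred == ens$cv_predictions$true)
  av <- predict(ens, sep$features[ens$holdout_ids, ], mode = "averaged")
  hold_correct <- sum(as.character(av$labels) ==
                        as.character(sep$labels[match(ens$holdout_ids,
                                                      rownames(sep$features))]))
  expect_equal(rep$combined_accuracy,
               (cv_correct + hold_correct) / nrow(sep$features))
  expect_equal(dim(rep$confusion$cv), c(3, 3))
  expect_equal(sum(rep$confusion$cv), rep$n_cv)
})
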
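test_that("permutation importance finds informative features and not noise", {
  set.seed(21)
  n <- 90
  classes <- survival_classes()
  y <- factor(rep(classes, each = n / 3), levels = classes)
  X <- cbind(signal = as.integer(y) * 4 + rnorm(n, sd = 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(X) <- sprintf("S%03d", 1:n)
  cfg <- classifier_config(outer_folds = 3, inner_folds = 1, holdout = 0,
                           max_epochs = 120, patience = 20)
  ens <- train_nested_cv(X, y, config = cfg, seed = 6)
  imp <- permutation_importance(ens, X, y, repeats = 200, seed = 9)
  s <- imp[imp$feature == "signal", ]
  # permuting the only informative feature drops accuracy toward chance
  expect_gt(s$importance, 0.4)
  for (nm in c("noise1", "noise2")) {
    r <- imp[imp$feature == nm, ]
    expect_lt(abs(r$importance), 2 * r$se + 1e-8)
  }
})

test_that("a feature the network ignores has exactly zero importance", {
  set.seed(5)
  sep <- make_separable_features(n_per_class = 12, seed = 5)
  cfg <- classifier_config(outer_folds = 3, inner_folds = 1, holdout = 0,
                           max_epochs = 40, patience = 10)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 2)
  # sever feature 2 from every member's first layer
  for (i in seq_along(ens$members)) {
    ens$members[[i]]$params$W[[1]][2, ] <- 0
  }
  imp <- permutation_importance(ens, sep$features, sep$labels,
                                repeats = 5, seed = 3)
  expect_equal(imp$importance[imp$feature == "f2"], 0)
})

test_that("repeats reduce the importance standard error", {
  sep <- make_separable_features(n_per_class = 12, gap = 1, seed = 9)
  cfg <- classifier_config(outer_folds = 3, inner_folds = 1, holdout = 0,
                           max_epochs = 60, patience = 10)
  ens <- train_nested_cv(sep$features, sep$labels, config = cfg, seed = 4)
  i1 <- permutation_importance(ens, sep$features, sep$labels,
                               repeats = 4, seed = 7)
  i2 <- permutation_importance(ens, sep$features, sep$labels,
                               repeats = 100, seed = 7)
  expect_lt(mean(i2$se), mean(i1$se))
  # same expectation: estimates agree within joint uncertainty
  expect_lt(max(abs(i1$importance - i2$importance) /
                  pmax(2 * (i1$se + i2$se), 0.05)), 1.5)
})

test_that("encoded importance is attributed through absolute encoder weights", {
  enc <- make_toy_encoder(input_labels = fc_pair_labels(), kept = c(2, 5, 9))
  imp <- setNames(c(0.3, 0.1, 0.2), paste0("FC", 1:3))

  # brute-force double loop over units x pairs
  W <- abs(enc$W1[, c(2, 5, 9)])
  raw <- numeric(120)
  for (j in 1:120) {
    for (u in 1:3) raw[j] <- raw[j] + imp[u] * W[j, u]
  }
  expected <- raw / sum(raw)
  got <- attribute_encoded_to_raw(enc, imp)
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_equal(sum(got), 1)

  # one-hot loading: all weight on a single pair
  enc1 <- make_toy_encoder(kept = 1)
  enc1$W1[] <- 0
  enc1$W1[which(fc_pair_labels() == "SMDxCON"), 1] <- 0.7
  got1 <- attribute_encoded_to_raw(enc1, c(FC1 = 0.4))
  expect_equal(unname(got1[["SMDxCON"]]), 1)
  expect_equal(sum(got1), 1)

  # uniform weights: uniform pair attribution
  encu <- make_toy_encoder(kept = 1:4)
  encu$W1[] <- 0.25
  gotu <- attribute_encoded_to_raw(encu, setNames(runif(4, 0.1, 0.5),
                                                  paste0("FC", 1:4)))
  expect_equal(unname(gotu), rep(1 / 120, 120))

  expect_error(attribute_encoded_to_raw(enc, c(FC1 = 0.1)), "schema error")
})

test_that("network averaging counts each network's incident pairs once", {
  labs <- fc_pair_labels()
  w <- setNames(rep(0.5, 120), labs)
  nw <- network_average_weights(w)
  expect_equal(nw$mean, rep(0.5, 15))
  expect_equal(nw$sd, rep(0, 15))
  expect_equal(nw$n_pairs, rep(15L, 15))

  w2 <- setNames(numeric(120), labs)
  w2["SMDxSMD"] <- 1
  nw2 <- network_average_weights(w2)
  expect_equal(nw2$mean[nw2$network == "SMD"], 1 / 15)
  expect_equal(sum(nw2$mean[nw2$network != "SMD"]), 0)

  # label-parsing oracle on random weights, plus order invariance
  set.seed(3)
  w3 <- setNames(runif(120), labs)
  nw3 <- network_average_weights(w3)
  for (net in c("SMD", "DMN", "BGA")) {
    sel <- sapply(strsplit(labs, "x"), function(p) net %in% p)
    expect_equal(nw3$mean[nw3$network == net], mean(w3[sel]))
    expect_equal(nw3$sd[nw3$network == net], sd(w3[sel]))
  }
  shuf <- sample(120)
  nw3b <- network_average_weights(w3[shuf])
  expect_equal(nw3b, nw3)
  expect_error(network_average_weights(w3[-1]), "schema error")
})

test_that("voxel projection is the advertised dot product and is linear", {
  cfg <- tiny_sim_config(n_networks = 4, voxels_per_network = 10, seed = 2)
  maps <- generate_probability_maps(cfg, grid_size = 100)
  nets <- names(maps)

  one_hot <- setNames(c(1, 0, 0, 0), nets)
  expect_equal(project_to_voxels(one_hot, maps), maps[[1]]$values)
  expect_equal(project_to_voxels(setNames(rep(0, 4), nets), maps),
               numeric(100))

  set.seed(6)
  w <- setNames(runif(4), nets)
  manual <- numeric(100)
  for (v in 1:100) {
    for (nw in nets) manual[v] <- manual[v] + w[[nw]] * maps[[nw]]$values[v]
  }
  expect_equal(project_to_voxels(w, maps), manual)

  w2 <- setNames(runif(4), nets)
  expect_equal(project_to_voxels(setNames(w + 2 * w2, nets), maps),
               project_to_voxels(w, maps) + 2 * project_to_voxels(w2, maps))
  expect_error(project_to_voxels(setNames(1, "XXX"), maps), "shape error")
})
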
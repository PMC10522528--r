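test_that("distance correlation matches the double-loop oracle", {
  set.seed(42)
  for (i in 1:50) {
    T_ <- sample(4:12, 1)
    X <- matrix(rnorm(T_ * sample(1:4, 1)), T_)
    Y <- matrix(rnorm(T_ * sample(1:4, 1)), T_)
    expect_lt(abs(distance_correlation(X, Y) - dcor_oracle(X, Y)), 1e-10)
  }
})

test_that("distance correlation has the defining invariances", {
  set.seed(7)
  X <- matrix(rnorm(24), 12, 2)
  x <- rnorm(9)
  expect_equal(distance_correlation(X, X), 1)
  expect_equal(distance_correlation(x, 2 * x + 3), 1)
  # symmetry and translation / positive-scaling invariance
  Y <- matrix(rnorm(36), 12, 3)
  expect_equal(distance_correlation(X, Y), distance_correlation(Y, X))
  expect_equal(distance_correlation(X, Y),
               distance_correlation(3 * X + 5, Y), tolerance = 1e-12)
  # zero distance variance contract
  expect_warning(z <- distance_correlation(rep(1, 6), rnorm(6)),
                 "zero distance variance")
  expect_equal(z, 0)
  expect_error(distance_correlation(matrix(rnorm(10), 5), matrix(rnorm(8), 4)),
               "shape error")
  expect_error(distance_correlation(c(1, NA, 3), 1:3), "non-finite")
})

test_that("within-network similarity matches leave-one-out enumeration", {
  set.seed(9)
  B <- matrix(rnorm(12 * 3), 12, 3)
  loo <- mean(sapply(1:3, function(v) dcor_oracle(B[, v], B[, -v])))
  expect_equal(within_network_similarity(B), loo, tolerance = 1e-10)
  pw <- mean(apply(combn(3, 2), 2,
                   function(p) dcor_oracle(B[, p[1]], B[, p[2]])))
  expect_equal(within_network_similarity(B, "pairwise"), pw,
               tolerance = 1e-10)
  # identical non-constant voxels: every term is a self-similarity
  ident <- matrix(rep(rnorm(10), 4), 10, 4)
  expect_equal(within_network_similarity(ident), 1)
  expect_error(within_network_similarity(matrix(1:5, ncol = 1)),
               "degenerate network")
})

test_that("between-network similarity is a single multivariate calculation", {
  set.seed(3)
  A <- matrix(rnorm(10 * 4), 10, 4)
  B <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(between_network_similarity(A, B), dcor_oracle(A, B),
               tolerance = 1e-10)
  expect_equal(between_network_similarity(A, A), 1)
  expect_equal(between_network_similarity(A, A[, c(3, 1, 4, 2)]), 1)
})

test_that("ROI selection takes the top-k voxels deterministically", {
  m <- structure(list(network = "SMD", values = c(0.9, 0.1, 0.5)),
                 class = "probability_map")
  expect_equal(select_roi(m, 2)$voxel_indices, c(1L, 3L))
  # exhaustive case with distinct values
  set.seed(1)
  v <- runif(20)
  m2 <- structure(list(network = "VIS", values = v),
                  class = "probability_map")
  expect_equal(select_roi(m2, 20)$voxel_indices, order(v, decreasing = TRUE))
  # full-sort oracle on a 300-positive-voxel map
  v3 <- numeric(500)
  v3[sample(500, 300)] <- runif(300)
  m3 <- structure(list(network = "DMN", values = v3),
                  class = "probability_map")
  ord <- order(-v3, seq_along(v3))
  expect_equal(select_roi(m3, 200)$voxel_indices, ord[1:200])
  # ties broken by ascending index
  m4 <- structure(list(network = "AUD", values = c(0.5, 0.7, 0.5, 0.2)),
                  class = "probability_map")
  expect_equal(select_roi(m4, 3)$voxel_indices, c(2L, 1L, 3L))
  expect_error(select_roi(m4, 5), "degenerate map")
})

test_that("connectome layout covers all pairs in canonical order", {
  set.seed(5)
  nets15 <- canonical_networks()
  blocks <- lapply(nets15, function(nw) matrix(rnorm(12 * 3), 12, 3))
  names(blocks) <- nets15
  ts <- structure(list(frames = 12, blocks = blocks),
                  class = "timeseries_set")
  cv <- build_connectome(ts)
  expect_length(cv, 120)
  expect_equal(names(cv), fc_pair_labels())
  expect_equal(names(cv)[1:3], c("SMDxSMD", "SMDxSMI", "SMDxCON"))
  expect_true(all(cv >= 0 & cv <= 1))

  # 3-network test mode
  ts3 <- structure(list(frames = 12, blocks = blocks[1:3]),
                   class = "timeseries_set")
  expect_length(build_connectome(ts3), 6)
  expect_error(build_connectome(ts3, networks = c("SMD", "VIS")),
               "schema error")
})

test_that("connectome values are covariant under block permutation", {
  set.seed(8)
  nets <- canonical_networks()[1:4]
  blocks <- lapply(nets, function(nw) matrix(rnorm(10 * 3), 10, 3))
  names(blocks) <- nets
  ts <- structure(list(frames = 10, blocks = blocks),
                  class = "timeseries_set")
  cv <- build_connectome(ts)
  perm <- structure(list(frames = 10, blocks = blocks[c(3, 1, 4, 2)]),
                    class = "timeseries_set")
  cv2 <- build_connectome(perm)  # canonical reordering restores layout
  expect_equal(cv2[names(cv)], cv)
})

test_that("identity coupling with zero noise gives unit within-similarity", {
  nets <- canonical_networks()[1:3]
  cfg <- sim_config(n_subjects = 1, n_networks = 3, voxels_per_network = 4,
                    n_frames = 25, noise_sd = 0,
                    coupling_matrices = default_coupling_matrices(
                      nets, base = 0, planted_pairs = character()),
                    seed = 12)
  coh <- generate_cohort(cfg)
  cv <- build_connectome(coh$timeseries[[1]])
  expect_equal(unname(cv[c("SMDxSMD", "SMIxSMI", "CONxCON")]), rep(1, 3))
})

test_that("between-network similarity is monotone in planted coupling", {
  nets <- canonical_networks()[1:2]
  vals <- sapply(c(0.1, 0.45, 0.8), function(r) {
    C <- default_coupling_matrices(nets, base = 0,
                                   planted_pairs = "SMDxSMI",
                                   planted_levels = rep(r, 3))
    cfg <- sim_config(n_subjects = 1, n_networks = 2, voxels_per_network = 5,
                      n_frames = 1500, noise_sd = 0.5,
                      coupling_matrices = C, seed = 14)
    ts <- generate_timeseries("LT1Y", cfg, seed = 15)
    between_network_similarity(ts$blocks$SMD, ts$blocks$SMI)
  })
  expect_true(all(diff(vals) > 0))
})
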
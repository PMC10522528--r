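# Independent oracles and fixture builders used across the suite.

# Brute-force distance correlation: explicit double-loop distance matrices
# and double-centering, straight from the defining sums.  Kept deliberately
# naive and separate from the package implementation.
dcor_oracle <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  T_ <- nrow(X)
  dmat <- function(M) {
    D <- matrix(0, T_, T_)
    for (j in seq_len(T_)) {
      for (k in seq_len(T_)) {
        D[j, k] <- sqrt(sum((M[j, ] - M[k, ])^2))
      }
    }
    D
  }
  center <- function(D) {
    A <- matrix(0, T_, T_)
    rm <- rowMeans(D); cm <- colMeans(D); g <- mean(D)
    for (j in seq_len(T_)) {
      for (k in seq_len(T_)) {
        A[j, k] <- D[j, k] - rm[j] - cm[k] + g
      }
    }
    A
  }
  A <- center(dmat(X)); B <- center(dmat(Y))
  dcov2 <- mean(A * B); dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# Low-rank factor data emulating a cohort of connectome vectors.
make_rank3_connectomes <- function(n = 200, p = 120, noise_sd = 0.15,
                                   seed = 11) {
  set.seed(seed)
  scores <- matrix(rnorm(n * 3), n, 3)
  loadings <- matrix(rnorm(3 * p), 3, p)
  X <- scores %*% loadings + matrix(rnorm(n * p, sd = noise_sd), n, p)
  colnames(X) <- fc_pair_labels()[seq_len(p)]
  X
}

# Widely separated 3-class feature set: class means far apart relative to
# noise, so any sane classifier is perfect.
make_separable_features <- function(n_per_class = 20, p = 5, gap = 10,
                                    seed = 1) {
  set.seed(seed)
  classes <- survival_classes()
  X <- do.call(rbind, lapply(seq_len(3L), function(g) {
    matrix(rnorm(n_per_class * p, mean = g * gap), n_per_class, p)
  }))
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(features = X,
       labels = factor(rep(classes, each = n_per_class), levels = classes))
}

# Minimal hand-built autoencoder object (identity-ish) for attribution and
# assembly tests that need a model without a full training run.
make_toy_encoder <- function(input_labels = fc_pair_labels(),
                             hidden_dim = 20, kept = seq_len(11), seed = 3) {
  set.seed(seed)
  p <- length(input_labels)
  structure(list(
    input_dim = p, hidden_dim = hidden_dim, input_labels = input_labels,
    center = rep(0, p), scale = rep(1, p),
    W1 = matrix(runif(p * hidden_dim, -0.5, 0.5), p, hidden_dim),
    b1 = numeric(hidden_dim),
    W2 = matrix(runif(hidden_dim * p, -0.5, 0.5), hidden_dim, p),
    b2 = numeric(p),
    training_log = data.frame(epoch = 1L, train = 0, validation = 0),
    best_epoch = 1L, activation = "tanh", input_gain = 0.2,
    kept_features = kept, val_idx = integer(0), seed = seed
  ), class = "autoencoder")
}

# Compact simulation configuration for fast end-to-end tests.
tiny_sim_config <- function(n_subjects = 60, n_networks = 4,
                            voxels_per_network = 6, n_frames = 40,
                            seed = 1, ...) {
  nets <- canonical_networks()[seq_len(n_networks)]
  sim_config(n_subjects = n_subjects,
             group_proportions = c(1, 1, 1) / 3,
             n_networks = n_networks,
             voxels_per_network = voxels_per_network,
             n_frames = n_frames,
             coupling_matrices = default_coupling_matrices(
               nets, planted_pairs = character()),
             seed = seed, ...)
}
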
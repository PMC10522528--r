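sigmoid <- function(z) 1 / (1 + exp(-z))

ae_act <- function(z, activation) {
  if (activation == "tanh") tanh(z) else sigmoid(z)
}

ae_losses <- function(Xs, W1, b1, W2, b2, activation) {
  H <- ae_act(sweep(Xs %*% W1, 2L, b1, "+"), activation)
  R <- sweep(H %*% W2, 2L, b2, "+")
  mean((R - Xs)^2)
}

#' Fit the functional-connectivity autoencoder
#'
#' Trains a single-hidden-layer autoencoder (20 saturating sigmoidal units
#' by default, linear reconstruction) on the cohort's connectome vectors by
#' full-batch gradient descent with momentum, minimizing mean squared
#' reconstruction error.  Inputs are standardized to zero mean / unit
#' variance with training-split statistics.  Training runs on a seeded 80%
#' split, with the remaining 20% reserved for validation termination: the
#' epoch with the lowest validation loss is kept, and training stops once
#' validation fails to improve for `patience` epochs.
#'
#' @param connectomes `n x p` matrix of connectome vectors (n >= 10), columns
#'   labeled by network pair.
#' @param hidden_dim Number of code units (default 20).
#' @param val_fraction Fraction of subjects held out for validation
#'   termination (default 0.2).
#' @param lr,momentum Optimizer settings (defaults 2, 0.9; the loss is
#'   averaged over all `n x p` entries, so gradients are small and a large
#'   nominal rate is appropriate).
#' @param max_epochs,patience Early-stopping budget (defaults 5000, 100).
#' @param activation Hidden-unit sigmoid: `"tanh"` (default; symmetric and
#'   near-linear at the origin, which trains faster on standardized data) or
#'   `"logistic"`.
#' @param input_gain Multiplier applied to the standardized inputs before
#'   the hidden layer (default 0.2).  Keeping pre-activations inside the
#'   sigmoid's quasi-linear range lets the code reach the accuracy of a
#'   truncated-SVD basis on low-rank data instead of stalling on saturation.
#' @param seed Seed for the split and the uniform `+/- 1/sqrt(fan-in)`
#'   weight initialization.
#' @return Object of class `autoencoder`: scaling statistics, weights at the
#'   best-validation epoch, `training_log` (epoch, train and validation
#'   loss), `best_epoch`, and `kept_features` (initially all units).
#' @export
fit_autoencoder <- function(connectomes, hidden_dim = 20, val_fraction = 0.2,
                            lr = 2, momentum = 0.9,
                            max_epochs = 5000, patience = 100,
                            activation = c("tanh", "logistic"),
                            input_gain = 0.2, seed = 1) {
  activation <- match.arg(activation)
  X <- as.matrix(connectomes)
  if (any(!is.finite(X))) stop("data error: non-finite connectome entries")
  n <- nrow(X); p <- ncol(X)
  n_val <- floor(n * val_fraction)
  if (n < 10L || n_val < 1L || n - n_val < 2L) {
    stop("size error: too few subjects (", n, ") to split for validation")
  }
  set.seed(as.integer(seed))
  val_idx <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val_idx)

  center <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2L, sd)
  scl[scl < 1e-12] <- 1  # constant columns pass through unscaled
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/") * input_gain
  Xtr <- Xs[tr, , drop = FALSE]
  Xval <- Xs[val_idx, , drop = FALSE]

  r1 <- 1 / sqrt(p); r2 <- 1 / sqrt(hidden_dim)
  W1 <- matrix(runif(p * hidden_dim, -r1, r1), p, hidden_dim)
  b1 <- numeric(hidden_dim)
  W2 <- matrix(runif(hidden_dim * p, -r2, r2), hidden_dim, p)
  b2 <- numeric(p)
  vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2

  ntr <- nrow(Xtr)
  log_tr <- numeric(max_epochs); log_val <- numeric(max_epochs)
  best_val <- Inf; best_epoch <- 0L; best <- NULL; stall <- 0L; ep <- 0L
  denom <- ntr * p
  for (ep in seq_len(max_epochs)) {
    H <- ae_act(sweep(Xtr %*% W1, 2L, b1, "+"), activation)
    R <- sweep(H %*% W2, 2L, b2, "+")
    E <- R - Xtr
    dR <- (2 / denom) * E
    gW2 <- crossprod(H, dR); gb2 <- colSums(dR)
    dact <- if (activation == "tanh") 1 - H^2 else H * (1 - H)
    dH <- tcrossprod(dR, W2) * dact
    gW1 <- crossprod(Xtr, dH); gb1 <- colSums(dH)
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2

    log_tr[ep] <- ae_losses(Xtr, W1, b1, W2, b2, activation)
    log_val[ep] <- ae_losses(Xval, W1, b1, W2, b2, activation)
    if (log_val[ep] < best_val - 1e-12) {
      best_val <- log_val[ep]; best_epoch <- ep
      best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(
    input_dim = p, hidden_dim = hidden_dim,
    input_labels = colnames(X),
    center = center, scale = scl,
    W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
    training_log = data.frame(epoch = seq_len(ep),
                              train = log_tr[seq_len(ep)],
                              validation = log_val[seq_len(ep)]),
    best_epoch = best_epoch,
    activation = activation, input_gain = input_gain,
    kept_features = seq_len(hidden_dim),
    val_idx = val_idx, seed = as.integer(seed)
  ), class = "autoencoder")
}

#' Prune sparse code units
#'
#' Drops code dimensions whose activation variance across the training
#' subjects falls below `tol_rel` times the most-active unit's variance
#' ("sparse" units that encode almost nothing).  Survivors are relabeled
#' `FC1..FCm` in original unit order; their values are unchanged.
#'
#' @param model A fitted [fit_autoencoder()] model.
#' @param connectomes Connectome matrix on which activation variance is
#'   measured (the training cohort).
#' @param tol_rel Relative variance tolerance (default 1e-4).
#' @return The model with `kept_features` updated.
#' @export
prune_sparse_features <- function(model, connectomes, tol_rel = 1e-4) {
  H <- encoder_activations(model, connectomes)
  v <- apply(H, 2L, var)
  keep <- which(v > tol_rel * max(v))
  if (length(keep) == 0L) {
    stop("degenerate code: every unit pruned at tol_rel = ", tol_rel)
  }
  model$kept_features <- keep
  model
}

encoder_activations <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop("shape error: expected ", model$input_dim, " inputs, got ", ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/") *
    model$input_gain
  ae_act(sweep(Xs %*% model$W1, 2L, model$b1, "+"), model$activation)
}

#' Encode connectome vectors
#'
#' Hidden-layer activations of the fitted autoencoder, restricted to the
#' kept (non-sparse) units and labeled `FC1..FCm`, after applying the
#' training-set input scaling.
#'
#' @param model A fitted [fit_autoencoder()] model (possibly pruned).
#' @param connectome A single connectome vector or an `n x p` matrix.
#' @return Numeric matrix `n x m` of encoded features, columns `FC1..FCm`.
#' @export
encode <- function(model, connectome) {
  H <- encoder_activations(model, connectome)
  H <- H[, model$kept_features, drop = FALSE]
  colnames(H) <- paste0("FC", seq_along(model$kept_features))
  H
}

#' Reconstruct connectome vectors through the autoencoder
#'
#' Decoder output on the original (unstandardized) scale; used to assess
#' reconstruction quality.
#'
#' @inheritParams encode
#' @return Matrix with the shape of the input.
#' @export
reconstruct <- function(model, connectome) {
  H <- encoder_activations(model, connectome)
  R <- sweep(H %*% model$W2, 2L, model$b2, "+") / model$input_gain
  sweep(sweep(R, 2L, model$scale, "*"), 2L, model$center, "+")
}
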
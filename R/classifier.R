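# Small feedforward softmax classifier trained with Adam.  The architecture
# (3 hidden layers of 8 ReLU units) follows the survival model; everything
# else is exposed through classifier_config().

mlp_init <- function(n_in, hidden, n_out, seed) {
  set.seed(as.integer(seed))
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    r <- sqrt(6 / sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -r, r),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_probs <- function(params, X) {
  L <- length(params$W)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- sweep(A %*% params$W[[l]], 2L, params$b[[l]], "+")
    A[A < 0] <- 0
  }
  Z <- sweep(A %*% params$W[[L]], 2L, params$b[[L]], "+")
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z)
  P / rowSums(P)
}

mlp_ce <- function(params, X, Y) {
  P <- mlp_probs(params, X)
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

# One Adam training run.  If Xval is given, early-stops on validation
# cross-entropy (patience epochs without improvement) and restores the best
# epoch; otherwise runs exactly max_epochs.
mlp_train <- function(X, Y, hidden = c(8, 8, 8), Xval = NULL, Yval = NULL,
                      lr = 0.01, max_epochs = 400, patience = 40,
                      weight_decay = 0.1, seed = 1) {
  n <- nrow(X); n_out <- ncol(Y)
  params <- mlp_init(ncol(X), hidden, n_out, seed)
  L <- length(params$W)
  m <- list(W = lapply(params$W, function(w) w * 0),
            b = lapply(params$b, function(v) v * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf; best_epoch <- 0L; best <- params; stall <- 0L
  use_val <- !is.null(Xval)
  for (ep in seq_len(max_epochs)) {
    acts <- vector("list", L + 1L)
    acts[[1L]] <- X
    for (l in seq_len(L - 1L)) {
      A <- sweep(acts[[l]] %*% params$W[[l]], 2L, params$b[[l]], "+")
      A[A < 0] <- 0
      acts[[l + 1L]] <- A
    }
    Z <- sweep(acts[[L]] %*% params$W[[L]], 2L, params$b[[L]], "+")
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    dZ <- (P - Y) / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(acts[[l]], dZ) + weight_decay * params$W[[l]]
      gb[[l]] <- colSums(dZ)
      if (l > 1L) {
        dZ <- tcrossprod(dZ, params$W[[l]]) * (acts[[l]] > 0)
      }
    }
    corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
    for (l in seq_len(L)) {
      m$W[[l]] <- b1 * m$W[[l]] + (1 - b1) * gW[[l]]
      v$W[[l]] <- b2 * v$W[[l]] + (1 - b2) * gW[[l]]^2
      params$W[[l]] <- params$W[[l]] -
        lr * (m$W[[l]] / corr1) / (sqrt(v$W[[l]] / corr2) + eps)
      m$b[[l]] <- b1 * m$b[[l]] + (1 - b1) * gb[[l]]
      v$b[[l]] <- b2 * v$b[[l]] + (1 - b2) * gb[[l]]^2
      params$b[[l]] <- params$b[[l]] -
        lr * (m$b[[l]] / corr1) / (sqrt(v$b[[l]] / corr2) + eps)
    }
    if (use_val) {
      vl <- mlp_ce(params, Xval, Yval)
      if (vl < best_val - 1e-9) {
        best_val <- vl; best_epoch <- ep; best <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (use_val) list(params = best, best_epoch = best_epoch)
  else list(params = params, best_epoch = max_epochs)
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

# Stratified fold ids: within each class, a seeded shuffle followed by
# round-robin assignment, so fold class counts differ by at most one.
stratified_folds <- function(labels, K, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

# Stratified fixed-size sample (largest remainder across classes).
stratified_sample <- function(labels, size, seed) {
  set.seed(as.integer(seed))
  tab <- table(labels)
  quota <- allocate_groups(size, as.numeric(tab) / sum(tab))
  picked <- integer(0)
  for (i in seq_along(tab)) {
    idx <- which(labels == names(tab)[i])
    picked <- c(picked, idx[sample.int(length(idx), min(quota[i], length(idx)))])
  }
  sort(picked)
}

#' Classifier configuration
#'
#' Settings for the nested stratified cross-validation of the survival
#' classifier.  Defaults: 10 outer folds, 5 inner folds for epoch selection,
#' a stratified global holdout of 10 subjects, and a 3-hidden-layer network
#' of 8 rectified units per layer with softmax output and cross-entropy
#' loss, trained with Adam and early stopping.
#'
#' @param outer_folds,inner_folds Nested cross-validation structure.
#'   `inner_folds = 1` uses a single stratified 80/20 validation split for
#'   epoch selection instead of inner folds.
#' @param holdout Size of the stratified global holdout (default 10).
#' @param hidden Hidden-layer widths (default `c(8, 8, 8)`).
#' @param lr,max_epochs,patience Optimizer and early-stopping settings.
#' @param weight_decay L2 penalty on the weights (default 0.1).  With many
#'   imaging features and ~10x fewer subjects the unpenalized network
#'   memorizes the training folds; ridge shrinkage keeps it on the few
#'   genuinely informative directions.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(outer_folds = 10, inner_folds = 5, holdout = 10,
                              hidden = c(8, 8, 8), lr = 0.01,
                              max_epochs = 400, patience = 40,
                              weight_decay = 0.1) {
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 holdout = as.integer(holdout),
                 hidden = hidden, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay),
            class = "classifier_config")
}

#' Assemble the classifier feature matrix
#'
#' Joins demographics (age, sex), the 34 contralesional cortical-thickness
#' parcels, and the encoded functional-connectivity features into one row
#' per subject, in cohort order, keyed by subject id.
#'
#' @param cohort A `gbm_cohort`.
#' @param connectomes Connectome matrix with subject-id rownames.
#' @param encoder_model A fitted (and typically pruned) autoencoder, or
#'   `NULL` to use the raw connectome columns instead of encoded features.
#' @return List with `features` (numeric matrix, rownames = subject ids) and
#'   `labels` (factor of survival classes).
#' @export
assemble_features <- function(cohort, connectomes, encoder_model = NULL) {
  subj <- cohort$subjects
  if (nrow(subj) == 0L) {
    return(list(features = matrix(numeric(0), 0L, 0L),
                labels = factor(character(0), levels = survival_classes())))
  }
  miss <- setdiff(subj$subject_id, rownames(connectomes))
  if (length(miss)) {
    stop("join error: subjects missing from connectome table: ",
         paste(miss, collapse = ", "))
  }
  fc <- connectomes[subj$subject_id, , drop = FALSE]
  if (!is.null(encoder_model)) fc <- encode(encoder_model, fc)
  ct <- as.matrix(subj[, sprintf("ct_%02d", 1:34)])
  X <- cbind(age = subj$age, sex = subj$sex, ct, fc)
  rownames(X) <- subj$subject_id
  list(features = X,
       labels = factor(subj$survival_class, levels = survival_classes()))
}

scale_features <- function(X, center, scl) {
  sweep(sweep(X, 2L, center), 2L, scl, "/")
}

# Training-fold scaling statistics; binary sex passes through unscaled.
fold_scaling <- function(X) {
  center <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  if ("sex" %in% colnames(X)) {
    center["sex"] <- 0; scl["sex"] <- 1
  }
  list(center = center, scale = scl)
}

#' Train the survival classifier under nested stratified cross-validation
#'
#' Reserves a stratified global holdout, partitions the remaining subjects
#' into stratified outer folds, selects the training length per outer fold
#' on inner validation folds (early stopping), trains one member network per
#' outer fold on that fold's training set, and records each non-holdout
#' subject's single out-of-fold prediction.  Feature scaling uses
#' training-fold statistics only.
#'
#' @param features Numeric matrix (rownames = subject ids).
#' @param labels Factor of survival classes aligned with `features`.
#' @param config A [classifier_config()].
#' @param seed Master seed for holdout, folds, and weight initialization.
#' @param holdout_ids Optional pre-chosen holdout subject ids (e.g. fixed
#'   before encoder training); when `NULL` a stratified holdout is drawn.
#' @return Object of class `gbm_ensemble`: `members` (weights, fold id,
#'   scaling statistics, epochs), `classes`, `cv_predictions` (per-subject
#'   out-of-fold prediction and class scores), `holdout_ids`.
#' @export
train_nested_cv <- function(features, labels, config = classifier_config(),
                            seed = 1, holdout_ids = NULL) {
  X <- as.matrix(features)
  labels <- factor(labels, levels = survival_classes())
  classes <- survival_classes()
  n <- nrow(X)
  seeds <- derive_seeds(seed, 3L + 2L * config$outer_folds)

  if (is.null(holdout_ids)) {
    hold_idx <- if (config$holdout > 0)
      stratified_sample(labels, config$holdout, seeds[1L]) else integer(0)
    holdout_ids <- rownames(X)[hold_idx]
  } else {
    hold_idx <- match(holdout_ids, rownames(X))
    if (any(is.na(hold_idx))) stop("unknown holdout subject id")
  }
  rest <- setdiff(seq_len(n), hold_idx)
  ylab <- labels[rest]
  if (any(table(ylab) < 3L)) {
    stop("stratification error: a class has fewer than 3 subjects ",
         "after holdout removal")
  }
  K <- config$outer_folds
  if (any(table(ylab) < K)) {
    stop("stratification error: a class has fewer members than the ",
         K, " outer folds")
  }
  fold <- stratified_folds(ylab, K, seeds[2L])

  members <- vector("list", K)
  pred <- character(length(rest))
  scores <- matrix(NA_real_, length(rest), length(classes),
                   dimnames = list(rownames(X)[rest], classes))
  for (f in seq_len(K)) {
    tr <- which(fold != f); te <- which(fold == f)
    Xtr <- X[rest[tr], , drop = FALSE]
    ytr <- ylab[tr]
    sc <- fold_scaling(Xtr)
    Xtr_s <- scale_features(Xtr, sc$center, sc$scale)
    Ytr <- one_hot(ytr, classes)
    seed_f <- seeds[3L + f]

    # inner loop: choose the number of epochs by early stopping
    if (config$inner_folds >= 2L) {
      ifold <- stratified_folds(ytr, config$inner_folds,
                                seeds[3L + K + f])
      eps_sel <- vapply(seq_len(config$inner_folds), function(g) {
        itr <- which(ifold != g); iva <- which(ifold == g)
        fit <- mlp_train(Xtr_s[itr, , drop = FALSE], Ytr[itr, , drop = FALSE],
                         hidden = config$hidden,
                         Xval = Xtr_s[iva, , drop = FALSE],
                         Yval = Ytr[iva, , drop = FALSE],
                         lr = config$lr, max_epochs = config$max_epochs,
                         patience = config$patience,
                         weight_decay = config$weight_decay,
                         seed = seed_f + g)
        fit$best_epoch
      }, 1)
      n_epochs <- max(10L, as.integer(round(mean(eps_sel))))
    } else {
      iva <- stratified_sample(ytr, max(2L, round(0.2 * length(ytr))),
                               seeds[3L + K + f])
      itr <- setdiff(seq_along(ytr), iva)
      fit <- mlp_train(Xtr_s[itr, , drop = FALSE], Ytr[itr, , drop = FALSE],
                       hidden = config$hidden,
                       Xval = Xtr_s[iva, , drop = FALSE],
                       Yval = Ytr[iva, , drop = FALSE],
                       lr = config$lr, max_epochs = config$max_epochs,
                       patience = config$patience,
                       weight_decay = config$weight_decay, seed = seed_f)
      n_epochs <- max(10L, fit$best_epoch)
    }
    final <- mlp_train(Xtr_s, Ytr, hidden = config$hidden,
                       lr = config$lr, max_epochs = n_epochs,
                       weight_decay = config$weight_decay, seed = seed_f)
    members[[f]] <- list(params = final$params, fold = f,
                         center = sc$center, scale = sc$scale,
                         epochs = n_epochs,
                         test_ids = rownames(X)[rest[te]])
    P <- mlp_probs(final$params,
                   scale_features(X[rest[te], , drop = FALSE],
                                  sc$center, sc$scale))
    scores[te, ] <- P
    pred[te] <- classes[max.col(P, ties.method = "first")]
  }
  cv_predictions <- data.frame(
    subject_id = rownames(X)[rest],
    fold = fold,
    true = as.character(ylab),
    pred = pred,
    stringsAsFactors = FALSE
  )
  structure(list(members = members, classes = classes,
                 cv_predictions = cv_predictions, cv_scores = scores,
                 holdout_ids = holdout_ids,
                 feature_names = colnames(X), config = config,
                 seed = as.integer(seed)),
            class = "gbm_ensemble")
}

member_probs <- function(member, newX) {
  mlp_probs(member$params, scale_features(newX, member$center, member$scale))
}

#' Predict survival classes from a trained ensemble
#'
#' `"averaged"` mode averages the class-score vectors of all member models
#' and takes the argmax (ties broken toward the worse prognosis, LT1Y);
#' `"per-model"` mode returns every member's own label.
#'
#' @param object A `gbm_ensemble`.
#' @param newdata Feature matrix with the training columns.
#' @param mode `"averaged"` or `"per-model"`.
#' @param ... Unused.
#' @return For `"averaged"`: list with `labels` (factor) and `scores`
#'   (matrix of mean class scores).  For `"per-model"`: list with `labels`
#'   (subjects x members character matrix) and `scores` (3-d array).
#' @export
predict.gbm_ensemble <- function(object, newdata,
                                 mode = c("averaged", "per-model"), ...) {
  mode <- match.arg(mode)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$feature_names)) {
    stop("shape error: expected ", length(object$feature_names),
         " features, got ", ncol(X))
  }
  classes <- object$classes
  probs <- lapply(object$members, member_probs, newX = X)
  if (mode == "averaged") {
    P <- Reduce(`+`, probs) / length(probs)
    labels <- factor(classes[max.col(P, ties.method = "first")],
                     levels = classes)
    dimnames(P) <- list(rownames(X), classes)
    list(labels = labels, scores = P)
  } else {
    lab <- vapply(probs, function(P) {
      classes[max.col(P, ties.method = "first")]
    }, character(nrow(X)))
    lab <- matrix(lab, nrow = nrow(X),
                  dimnames = list(rownames(X),
                                  paste0("model", seq_along(probs))))
    arr <- array(unlist(probs),
                 dim = c(nrow(X), length(classes), length(probs)),
                 dimnames = list(rownames(X), classes, NULL))
    list(labels = lab, scores = arr)
  }
}

confusion3 <- function(true, pred, classes) {
  table(factor(true, levels = classes), factor(pred, levels = classes),
        dnn = c("true", "pred"))
}

#' Evaluate a trained ensemble
#'
#' Computes the four headline accuracies: cross-validation accuracy over
#' out-of-fold predictions, holdout accuracy pooled over member-model x
#' held-out-subject pairs (with the per-model mean reported alongside),
#' combined accuracy (correct CV + correct holdout over all subjects, with
#' holdout correctness taken from the averaged-ensemble prediction), and
#' ensemble accuracy (averaged mode on the holdout).  Confusion matrices
#' accompany each evaluation.
#'
#' @param ensemble A `gbm_ensemble`.
#' @param features Full feature matrix (rownames = subject ids) including
#'   the holdout subjects.
#' @param labels Factor of true classes aligned with `features`.
#' @return List of class `accuracy_report`.
#' @export
evaluate_ensemble <- function(ensemble, features, labels) {
  X <- as.matrix(features)
  labels <- factor(labels, levels = ensemble$classes)
  names(labels) <- rownames(X)
  cvp <- ensemble$cv_predictions
  if (any(cvp$subject_id %in% ensemble$holdout_ids)) {
    stop("leakage error: holdout subject has an out-of-fold prediction")
  }
  cv_correct <- sum(cvp$pred == cvp$true)
  cv_accuracy <- cv_correct / nrow(cvp)

  hold <- ensemble$holdout_ids
  holdout_accuracy <- NA_real_; per_model_mean <- NA_real_
  ensemble_accuracy <- NA_real_; hold_correct <- 0L
  conf_hold <- NULL; conf_ens <- NULL
  if (length(hold)) {
    Xh <- X[hold, , drop = FALSE]
    yh <- labels[hold]
    pm <- predict(ensemble, Xh, mode = "per-model")
    hits <- pm$labels == matrix(as.character(yh), nrow(Xh),
                                ncol(pm$labels))
    holdout_accuracy <- mean(hits)          # pooled over model x subject
    per_model_mean <- mean(colMeans(hits))  # identical subjects per model
    av <- predict(ensemble, Xh, mode = "averaged")
    ensemble_accuracy <- mean(av$labels == yh)
    hold_correct <- sum(av$labels == yh)
    conf_hold <- confusion3(rep(as.character(yh), ncol(pm$labels)),
                            as.character(pm$labels), ensemble$classes)
    conf_ens <- confusion3(yh, av$labels, ensemble$classes)
  }
  combined_accuracy <- (cv_correct + hold_correct) /
    (nrow(cvp) + length(hold))
  structure(list(
    cv_accuracy = cv_accuracy,
    holdout_accuracy = holdout_accuracy,
    holdout_accuracy_per_model_mean = per_model_mean,
    combined_accuracy = combined_accuracy,
    ensemble_accuracy = ensemble_accuracy,
    n_cv = nrow(cvp), n_holdout = length(hold),
    confusion = list(
      cv = confusion3(cvp$true, cvp$pred, ensemble$classes),
      holdout_per_model = conf_hold,
      holdout_ensemble = conf_ens
    )
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("CV accuracy:       %.1f%% (n = %d)\n",
              100 * x$cv_accuracy, x$n_cv))
  if (x$n_holdout > 0) {
    cat(sprintf("Holdout accuracy:  %.1f%% (pooled, n = %d)\n",
                100 * x$holdout_accuracy, x$n_holdout))
    cat(sprintf("Ensemble accuracy: %.1f%% (averaged models)\n",
                100 * x$ensemble_accuracy))
  }
  cat(sprintf("Combined accuracy: %.1f%%\n", 100 * x$combined_accuracy))
  invisible(x)
}
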
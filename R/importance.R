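#' Permutation feature importance
#'
#' For every input feature, the drop in accuracy when that feature's column
#' is randomly permuted across subjects, averaged over permutation repeats
#' and ensemble members.  By default each member is evaluated on its own
#' out-of-fold subjects, so the importance is free of training-set optimism;
#' `scope = "all"` evaluates every member on all supplied subjects instead.
#'
#' @param ensemble A trained `gbm_ensemble`.
#' @param features Feature matrix (rownames = subject ids) covering at least
#'   the cross-validation subjects.
#' @param labels Factor of true classes aligned with `features`.
#' @param repeats Number of permutations per feature (default 100).
#' @param seed Seed for the permutations.
#' @param scope `"oof"` (out-of-fold, default) or `"all"`.
#' @return Data frame of class `importance_table` with columns `feature`,
#'   `importance` (mean accuracy drop) and `se` (standard error over
#'   repeats of the member-averaged drop).
#' @export
permutation_importance <- function(ensemble, features, labels, repeats = 100,
                                   seed = 1, scope = c("oof", "all")) {
  scope <- match.arg(scope)
  X <- as.matrix(features)
  if (ncol(X) != length(ensemble$feature_names)) {
    stop("shape error: expected ", length(ensemble$feature_names),
         " features, got ", ncol(X))
  }
  labels <- factor(labels, levels = ensemble$classes)
  names(labels) <- rownames(X)
  classes <- ensemble$classes
  members <- ensemble$members
  eval_sets <- lapply(members, function(m) {
    ids <- if (scope == "oof") intersect(m$test_ids, rownames(X))
           else rownames(X)
    if (length(ids) == 0L) stop("no evaluation subjects for a member")
    list(X = X[ids, , drop = FALSE], y = as.character(labels[ids]))
  })
  base_acc <- vapply(seq_along(members), function(i) {
    P <- member_probs(members[[i]], eval_sets[[i]]$X)
    mean(classes[max.col(P, ties.method = "first")] == eval_sets[[i]]$y)
  }, 1)

  set.seed(as.integer(seed))
  p <- ncol(X)
  drops <- matrix(0, repeats, p, dimnames = list(NULL, colnames(X)))
  for (r in seq_len(repeats)) {
    for (f in seq_len(p)) {
      acc <- vapply(seq_along(members), function(i) {
        Xi <- eval_sets[[i]]$X
        Xi[, f] <- Xi[sample.int(nrow(Xi)), f]
        P <- member_probs(members[[i]], Xi)
        mean(classes[max.col(P, ties.method = "first")] == eval_sets[[i]]$y)
      }, 1)
      drops[r, f] <- mean(base_acc - acc)
    }
  }
  out <- data.frame(feature = colnames(X),
                    importance = colMeans(drops),
                    se = apply(drops, 2L, sd) / sqrt(repeats),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Attribute encoded-feature importance to raw network pairs
#'
#' Distributes the importance of each kept encoded feature over the 120 raw
#' connectome pairs in proportion to the absolute encoder weight linking
#' each raw input to that code unit, then normalizes the pair weights to sum
#' to 1.  Negative encoded importances are clamped at zero before
#' attribution (a feature whose permutation *helps* carries no evidence).
#'
#' @param model The autoencoder used to produce the encoded features.
#' @param per_feature An `importance_table` (or named vector) containing
#'   entries `FC1..FCm` for every kept unit.
#' @return Named numeric vector of pair weights summing to 1, in the
#'   encoder's input-column order.
#' @export
attribute_encoded_to_raw <- function(model, per_feature) {
  if (is.data.frame(per_feature)) {
    imp <- setNames(per_feature$importance, per_feature$feature)
  } else {
    imp <- per_feature
  }
  fc_names <- paste0("FC", seq_along(model$kept_features))
  if (!all(fc_names %in% names(imp))) {
    stop("schema error: importance missing for ",
         paste(setdiff(fc_names, names(imp)), collapse = ", "))
  }
  w_enc <- pmax(imp[fc_names], 0)
  W <- abs(model$W1[, model$kept_features, drop = FALSE])
  raw <- as.numeric(W %*% w_enc)
  names(raw) <- model$input_labels
  tot <- sum(raw)
  if (tot <= 0) {
    warning("all encoded importances are non-positive; returning uniform ",
            "pair weights")
    return(setNames(rep(1 / length(raw), length(raw)), names(raw)))
  }
  raw / tot
}

#' Average feature weights per network
#'
#' For each network, the mean and standard deviation of the weights of all
#' pairs that involve it: its self-pair plus its pairs with every other
#' network (15 incident pairs per network in the 15-network connectome).
#'
#' @param pair_weights Named numeric vector with `"AxB"` labels covering all
#'   unordered pairs of the networks present.
#' @return Data frame with columns `network`, `mean`, `sd`, `n_pairs`,
#'   ordered by canonical network order.
#' @export
network_average_weights <- function(pair_weights) {
  labs <- names(pair_weights)
  if (is.null(labs)) stop("pair weights must be labeled")
  pp <- parse_pair_labels(labs)
  networks <- unique(as.vector(t(pp)))
  canon <- canonical_networks()
  networks <- c(intersect(canon, networks), setdiff(networks, canon))
  expected <- fc_pair_labels(networks)
  missing <- setdiff(expected, labs)
  if (length(missing)) {
    stop("schema error: missing pair label(s): ",
         paste(head(missing, 5L), collapse = ", "))
  }
  res <- lapply(networks, function(nw) {
    sel <- pp[, 1L] == nw | pp[, 2L] == nw
    w <- pair_weights[sel]
    data.frame(network = nw, mean = mean(w), sd = sd(w),
               n_pairs = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Project network weights onto voxel probability maps
#'
#' Voxelwise feature map: each voxel's value is the dot product of the
#' per-network average weights with the networks' probability-map values at
#' that voxel, `v = sum_n w_n * P_n(v)`.
#'
#' @param network_weights Named numeric vector of per-network weights, or
#'   the data frame returned by [network_average_weights()] (its `mean`
#'   column is used).
#' @param maps List of `probability_map` objects on a common grid, covering
#'   every weighted network.
#' @return Numeric vector over the voxel grid.
#' @export
project_to_voxels <- function(network_weights, maps) {
  if (is.data.frame(network_weights)) {
    network_weights <- setNames(network_weights$mean,
                                network_weights$network)
  }
  map_nets <- vapply(maps, function(m) m$network, "")
  missing <- setdiff(names(network_weights), map_nets)
  if (length(missing)) {
    stop("shape error: no probability map for ",
         paste(missing, collapse = ", "))
  }
  sizes <- vapply(maps, function(m) length(m$values), 1L)
  if (length(unique(sizes)) != 1L) {
    stop("shape error: probability maps disagree on grid size")
  }
  out <- numeric(sizes[1L])
  for (nw in names(network_weights)) {
    out <- out + network_weights[[nw]] *
      maps[[which(map_nets == nw)[1L]]]$values
  }
  out
}

#' Full importance report
#'
#' Bundles per-feature permutation importance, the back-attributed raw
#' network-pair weights, the per-network averages, and (when probability
#' maps are supplied) the voxelwise projection.  Age, sex and cortical
#' thickness bypass the encoder attribution and appear only in the
#' per-feature table.
#'
#' @inheritParams permutation_importance
#' @param encoder_model The autoencoder behind the `FC*` features.
#' @param maps Optional list of probability maps for the voxel projection.
#' @return List of class `importance_report` with elements `per_feature`,
#'   `per_fc_pair`, `per_network`, `voxel_map`.
#' @export
importance_report <- function(ensemble, features, labels, encoder_model,
                              repeats = 100, seed = 1, maps = NULL,
                              scope = c("oof", "all")) {
  per_feature <- permutation_importance(ensemble, features, labels,
                                        repeats = repeats, seed = seed,
                                        scope = match.arg(scope))
  per_fc_pair <- attribute_encoded_to_raw(encoder_model, per_feature)
  per_network <- network_average_weights(per_fc_pair)
  voxel_map <- if (!is.null(maps)) {
    project_to_voxels(setNames(per_network$mean, per_network$network), maps)
  }
  structure(list(per_feature = per_feature, per_fc_pair = per_fc_pair,
                 per_network = per_network, voxel_map = voxel_map),
            class = "importance_report")
}
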
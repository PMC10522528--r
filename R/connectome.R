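#' Select a network ROI from a probability map
#'
#' Takes the `k` voxels with the largest membership probabilities (the
#' "top-k" rule used to derive 200-voxel network ROIs), breaking ties by
#' ascending voxel index for determinism.
#'
#' @param map A `probability_map` (list with `network` and `values`).
#' @param k Number of voxels to retain (default 200).
#' @return Object of class `network_roi`: `network` and integer
#'   `voxel_indices` of length `k`, sorted by descending probability then
#'   ascending index.
#' @export
select_roi <- function(map, k = 200) {
  values <- map$values
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("probability map entries must be finite and in [0, 1]")
  }
  pos <- sum(values > 0)
  if (pos < k) {
    stop("degenerate map: only ", pos, " strictly positive voxels, need ", k)
  }
  ord <- order(-values, seq_along(values))
  structure(list(network = map$network,
                 voxel_indices = ord[seq_len(k)]),
            class = "network_roi")
}

as_sample_matrix <- function(X, arg) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite entries in ", arg)
  X
}

#' Distance correlation (V-statistic)
#'
#' Szekely's distance correlation between two multivariate samples observed
#' over the same `T` rows.  From the Euclidean distance matrices
#' `a_jk = ||X_j - X_k||` and `b_jk = ||Y_j - Y_k||`, each is double-centered
#' (`A_jk = a_jk - rowmean_j - colmean_k + grandmean`), and
#' `dCov^2 = sum(A * B) / T^2`, `dVar^2` analogously; the returned value is
#' `sqrt(dCov^2 / sqrt(dVar^2_X * dVar^2_Y))`, which lies in `[0, 1]`.
#' The biased V-statistic estimator is used (not the unbiased U-statistic),
#' matching the original definition and keeping the value in the unit
#' interval.
#'
#' @param X,Y Numeric matrices (or vectors) with the same number of rows
#'   `T >= 2`; columns are dimensions of each sample.
#' @return Scalar in `[0, 1]`.  If either sample has zero distance variance
#'   (e.g. a constant series), returns 0 with a warning.
#' @export
distance_correlation <- function(X, Y) {
  X <- as_sample_matrix(X, "X")
  Y <- as_sample_matrix(Y, "Y")
  if (nrow(X) != nrow(Y)) {
    stop("shape error: X has ", nrow(X), " rows but Y has ", nrow(Y))
  }
  if (nrow(X) < 2L) stop("need at least 2 observations")
  val <- cpp_dcor(X, Y)
  if (val == 0 && (all(X == X[1L, 1L]) || all(Y == Y[1L, 1L]))) {
    warning("zero distance variance; returning 0")
  }
  val
}

#' Within-network similarity
#'
#' Averages, over the voxels of one network block, the distance correlation
#' between each voxel's series and the remaining `k - 1` voxels treated as a
#' single multivariate sample (the default, set-based reading).  The
#' alternative `"pairwise"` method averages the univariate distance
#' correlation over all voxel pairs instead.
#'
#' @param block `T x k` matrix of one network's voxel time series, `k >= 2`.
#' @param method `"set"` (default) or `"pairwise"`.
#' @return Scalar in `[0, 1]`.
#' @export
within_network_similarity <- function(block, method = c("set", "pairwise")) {
  method <- match.arg(method)
  block <- as_sample_matrix(block, "block")
  if (ncol(block) < 2L) stop("degenerate network: need at least 2 voxels")
  if (nrow(block) < 2L) stop("need at least 2 frames")
  if (method == "set") cpp_within_set(block) else cpp_within_pairwise(block)
}

#' Between-network similarity
#'
#' Distance correlation between two network blocks, each treated as one
#' multivariate sample (all voxels enter a single calculation).
#'
#' @param blockA,blockB `T x k` matrices sharing `T`.
#' @return Scalar in `[0, 1]`.
#' @export
between_network_similarity <- function(blockA, blockB) {
  distance_correlation(blockA, blockB)
}

#' Build a subject's connectome vector
#'
#' Computes all within- and between-network distance-correlation
#' similarities of a time-series set and lays them out over the unordered
#' network pairs (self-pairs included) in upper-triangle row-major order of
#' the canonical network listing; for 15 networks this is the 120-element
#' connectome vector.
#'
#' @param ts A `timeseries_set` (list with `frames` and named `blocks`).
#' @param networks Network order to use; defaults to the canonical order
#'   restricted to the blocks present.  All requested blocks must exist.
#' @param within_method Passed to [within_network_similarity()].
#' @return Named numeric vector of length `n(n+1)/2` with `"AxB"` labels,
#'   class `connectome_vector`.
#' @export
build_connectome <- function(ts, networks = NULL,
                             within_method = c("set", "pairwise")) {
  within_method <- match.arg(within_method)
  blocks <- ts$blocks
  if (is.null(networks)) {
    networks <- intersect(canonical_networks(), names(blocks))
    if (length(networks) == 0L) networks <- names(blocks)
  }
  missing <- setdiff(networks, names(blocks))
  if (length(missing)) {
    stop("schema error: missing network block(s): ",
         paste(missing, collapse = ", "))
  }
  Ts <- vapply(blocks[networks], nrow, 1L)
  if (length(unique(Ts)) != 1L) stop("blocks disagree on frame count")
  blk <- lapply(blocks[networks], function(b) {
    b <- as.matrix(b); storage.mode(b) <- "double"; b
  })
  res <- cpp_connectome(blk, within_method == "pairwise")
  n <- length(networks)
  labs <- fc_pair_labels(networks)
  values <- numeric(length(labs))
  idx <- 1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      values[idx] <- if (i == j) res$within[i] else res$between[i, j]
      idx <- idx + 1L
    }
  }
  names(values) <- labs
  class(values) <- c("connectome_vector", "numeric")
  values
}

#' Build the cohort connectome table
#'
#' Applies [build_connectome()] to every subject of a cohort.
#'
#' @param cohort A `gbm_cohort` with time series.
#' @param within_method Passed to [build_connectome()].
#' @return Numeric matrix, one row per subject (rownames = subject ids),
#'   one labeled column per network pair.
#' @export
build_connectome_table <- function(cohort,
                                   within_method = c("set", "pairwise")) {
  within_method <- match.arg(within_method)
  if (is.null(cohort$timeseries)) stop("cohort has no time series")
  rows <- lapply(cohort$timeseries, build_connectome,
                 within_method = within_method)
  tab <- do.call(rbind, lapply(rows, as.numeric))
  colnames(tab) <- names(rows[[1L]])
  rownames(tab) <- names(cohort$timeseries)
  tab
}
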
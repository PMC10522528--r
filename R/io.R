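# Plain-text artifact I/O.  Cohort tables and connectomes travel as CSV,
# per-subject time series as one delimited matrix per subject with a header
# naming the network blocks, probability maps as a dense CSV with a JSON
# sidecar naming the networks.

#' Write / read a cohort table
#'
#' Columns: `subject_id, age, sex, ct_01..ct_34, survival_months, event,
#' survival_class`.
#'
#' @param cohort A `gbm_cohort` (or its `subjects` data frame).
#' @param path Output CSV path.
#' @return `write_cohort_csv`: the path, invisibly.  `read_cohort_csv`: the
#'   subjects data frame with `survival_class` releveled.
#' @export
write_cohort_csv <- function(cohort, path) {
  subj <- if (inherits(cohort, "gbm_cohort")) cohort$subjects else cohort
  write.csv(subj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  subj <- read.csv(path, stringsAsFactors = FALSE)
  subj$survival_class <- factor(subj$survival_class,
                                levels = survival_classes())
  subj
}

#' Write / read one subject's time-series matrix
#'
#' Tab-delimited matrix, rows = frames, columns named `NETWORK_v` per voxel.
#'
#' @param ts A `timeseries_set`.
#' @param path Output path.
#' @return `read_timeseries`: a `timeseries_set` (without latents).
#' @export
write_timeseries <- function(ts, path) {
  M <- do.call(cbind, lapply(names(ts$blocks), function(nw) {
    b <- ts$blocks[[nw]]
    colnames(b) <- paste0(nw, "_", seq_len(ncol(b)))
    b
  }))
  write.table(M, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  M <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE))
  nets <- sub("_[0-9]+$", "", colnames(M))
  blocks <- lapply(unique(nets), function(nw) {
    b <- M[, nets == nw, drop = FALSE]
    colnames(b) <- NULL
    b
  })
  names(blocks) <- unique(nets)
  structure(list(frames = nrow(M), blocks = blocks), class = "timeseries_set")
}

#' Write / read probability maps
#'
#' Dense CSV (one column per network, one row per grid voxel) plus a JSON
#' sidecar listing the networks and grid size.
#'
#' @param maps List of `probability_map` objects.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `read_probability_maps`: list of `probability_map` objects.
#' @export
write_probability_maps <- function(maps, path) {
  M <- vapply(maps, function(m) m$values, numeric(length(maps[[1L]]$values)))
  colnames(M) <- vapply(maps, function(m) m$network, "")
  write.csv(M, path, row.names = FALSE)
  jsonlite::write_json(
    list(networks = colnames(M), grid_size = nrow(M)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_probability_maps
#' @export
read_probability_maps <- function(path) {
  M <- as.matrix(read.csv(path, check.names = FALSE))
  maps <- lapply(colnames(M), function(nw) {
    structure(list(network = nw, values = unname(M[, nw])),
              class = "probability_map")
  })
  names(maps) <- colnames(M)
  maps
}

#' Write / read a connectome table
#'
#' CSV with `subject_id` plus one labeled column per network pair.
#'
#' @param connectomes Matrix from [build_connectome_table()].
#' @param path Output CSV path.
#' @return `read_connectomes_csv`: the matrix with subject-id rownames.
#' @export
write_connectomes_csv <- function(connectomes, path) {
  df <- data.frame(subject_id = rownames(connectomes), connectomes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectomes_csv
#' @export
read_connectomes_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df$subject_id
  M
}
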
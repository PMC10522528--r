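#' Default group-dependent network-coupling matrices
#'
#' Builds one symmetric coupling matrix per survival group over a constant
#' background coupling, with a small set of "planted" network pairs whose
#' coupling changes monotonically across groups.  The coupling matrix is used
#' as the covariance of the latent network signals, so entries must form a
#' positive-definite matrix with unit diagonal.
#'
#' @param networks Character vector of network codes.
#' @param base Background coupling between all network pairs (default 0.30,
#'   a typical between-network dependence level).
#' @param planted_pairs Character vector of `"AxB"` labels carrying
#'   group-dependent coupling; defaults to `SMDxCON`, `SMDxVIS`, `SMIxDMN`,
#'   the somatomotor/cinguloopercular/visual/default-mode pairs most
#'   implicated in survival.
#' @param planted_levels Numeric length-3 coupling value of every planted
#'   pair in groups LT1Y, Y1TO2, GT2Y respectively.
#' @return Named list of three symmetric unit-diagonal matrices.
#' @export
default_coupling_matrices <- function(networks = canonical_networks(),
                                      base = 0.30,
                                      planted_pairs = c("SMDxCON", "SMDxVIS",
                                                        "SMIxDMN"),
                                      planted_levels = c(0.15, 0.40, 0.65)) {
  n <- length(networks)
  stopifnot(length(planted_levels) == 3L)
  proto <- matrix(base, n, n, dimnames = list(networks, networks))
  diag(proto) <- 1
  out <- lapply(seq_len(3L), function(g) {
    C <- proto
    if (length(planted_pairs)) {
      pp <- parse_pair_labels(planted_pairs)
      for (r in seq_len(nrow(pp))) {
        C[pp[r, 1L], pp[r, 2L]] <- planted_levels[g]
        C[pp[r, 2L], pp[r, 1L]] <- planted_levels[g]
      }
    }
    C
  })
  names(out) <- survival_classes()
  out
}

#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the synthetic-cohort
#' generator.  The defaults emulate the study conditions: 133 subjects split
#' roughly 45/30/25% across the three survival classes, 15 networks of 200
#' voxels observed over ~320 BOLD frames (two concatenated runs), cortical
#' thinning of 0.15 mm per class over a ~2.2-3.1 mm Desikan-Killiany
#' baseline, a 4-year age shift per class, and class-consistent lognormal
#' survival times.
#'
#' @param n_subjects Number of subjects (default 133).
#' @param group_proportions Length-3 fractions for classes LT1Y, Y1TO2, GT2Y;
#'   must sum to 1.
#' @param n_networks,voxels_per_network,n_frames Dimensions of each subject's
#'   BOLD matrix (defaults 15, 200, 320).
#' @param coupling_matrices List of 3 symmetric unit-diagonal matrices
#'   (one per group); default [default_coupling_matrices()].
#' @param noise_sd Voxelwise iid noise sd added to the unit-variance latent
#'   network signal (default 1, i.e. noise on par with signal).
#' @param ct_baseline 34 positive parcel thicknesses in mm.
#' @param ct_group_shift Per-group additive shift in mm (default
#'   `c(-0.15, 0, 0.15)`: thinner cortex with worse prognosis).
#' @param ct_noise_sd Between-subject parcel thickness sd in mm (default 0.12).
#' @param age_mean_by_group,age_sd Age model in years (default means
#'   66/62/58, sd 8: older patients fare worse).
#' @param sex_prob_by_group Per-group probability of male sex.
#' @param survival_scale_by_group Lognormal scale (median, months) per group;
#'   times are drawn truncated to the group's class interval.
#' @param survival_sdlog Lognormal shape parameter (default 0.4).
#' @param censor_rate Probability that a subject's event indicator is 0
#'   (default 0: overall survival with death observed).
#' @param seed Master seed; every random draw in the generator derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 133,
                       group_proportions = c(0.45, 0.30, 0.25),
                       n_networks = 15,
                       voxels_per_network = 200,
                       n_frames = 320,
                       coupling_matrices = NULL,
                       noise_sd = 1,
                       ct_baseline = NULL,
                       ct_group_shift = c(-0.15, 0, 0.15),
                       ct_noise_sd = 0.12,
                       age_mean_by_group = c(66, 62, 58),
                       age_sd = 8,
                       sex_prob_by_group = c(0.68, 0.56, 0.44),
                       survival_scale_by_group = c(7, 17, 32),
                       survival_sdlog = 0.4,
                       censor_rate = 0,
                       seed = 1) {
  networks <- canonical_networks()[seq_len(n_networks)]
  if (n_networks > 15) {
    networks <- c(canonical_networks(),
                  sprintf("NET%02d", seq_len(n_networks - 15L)))
  }
  if (is.null(coupling_matrices)) {
    planted <- if (n_networks >= 7) c("SMDxCON", "SMDxVIS", "SMIxDMN") else character()
    coupling_matrices <- default_coupling_matrices(networks,
                                                   planted_pairs = planted)
  }
  if (is.null(ct_baseline)) {
    ct_baseline <- round(seq(2.2, 3.1, length.out = 34), 3)
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    group_proportions = group_proportions,
    n_networks = as.integer(n_networks),
    voxels_per_network = as.integer(voxels_per_network),
    n_frames = as.integer(n_frames),
    networks = networks,
    coupling_matrices = coupling_matrices,
    noise_sd = noise_sd,
    ct_baseline = ct_baseline,
    ct_group_shift = ct_group_shift,
    ct_noise_sd = ct_noise_sd,
    age_mean_by_group = age_mean_by_group,
    age_sd = age_sd,
    sex_prob_by_group = sex_prob_by_group,
    survival_scale_by_group = survival_scale_by_group,
    survival_sdlog = survival_sdlog,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 0 || n_networks < 1 || voxels_per_network < 1 ||
        n_frames < 2) {
      stop("configuration error: non-positive cohort dimensions")
    }
    if (length(group_proportions) != 3L ||
        abs(sum(group_proportions) - 1) > 1e-9 || any(group_proportions < 0)) {
      stop("configuration error: group_proportions must be 3 non-negative ",
           "fractions summing to 1")
    }
    if (length(coupling_matrices) != 3L) {
      stop("configuration error: need one coupling matrix per group")
    }
    for (C in coupling_matrices) {
      if (!isTRUE(all.equal(dim(C), rep(n_networks, 2L))) ||
          max(abs(C - t(C))) > 1e-12 || any(abs(diag(C) - 1) > 1e-12)) {
        stop("configuration error: coupling matrices must be symmetric ",
             n_networks, "x", n_networks, " with unit diagonal")
      }
      if (any(C < 0 | C > 1)) {
        stop("configuration error: coupling entries must lie in [0, 1]")
      }
      if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
        stop("configuration error: coupling matrix is not positive definite")
      }
    }
    if (length(ct_baseline) != 34L || any(ct_baseline <= 0)) {
      stop("configuration error: ct_baseline must be 34 positive thicknesses")
    }
    if (noise_sd < 0 || ct_noise_sd < 0 || age_sd <= 0 || survival_sdlog <= 0) {
      stop("configuration error: negative noise scale")
    }
    if (any(survival_scale_by_group <= 0)) {
      stop("configuration error: survival scales must be positive")
    }
    if (censor_rate < 0 || censor_rate > 1) {
      stop("configuration error: censor_rate must be in [0, 1]")
    }
  })
  invisible(cfg)
}

# Largest-remainder allocation of n subjects to 3 groups.
allocate_groups <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Truncated-lognormal survival times inside a class interval.
draw_survival <- function(n, scale, sdlog, interval) {
  lo <- plnorm(interval[1], meanlog = log(scale), sdlog = sdlog)
  hi <- plnorm(interval[2], meanlog = log(scale), sdlog = sdlog)
  u <- runif(n, lo, hi)
  qlnorm(u, meanlog = log(scale), sdlog = sdlog)
}

#' Generate one subject's BOLD time-series set
#'
#' Draws latent network signals from a multivariate normal with covariance
#' equal to the group's coupling matrix, then sets every voxel to its
#' network's latent plus iid normal noise with sd `noise_sd`.
#'
#' @param group Survival class of the subject (selects the coupling matrix).
#' @param config A [sim_config()].
#' @param seed Seed for this subject's draw.
#' @return Object of class `timeseries_set`: `frames`, named list `blocks`
#'   of `n_frames x voxels_per_network` matrices, and the latent matrix used
#'   (kept for diagnostics).
#' @export
generate_timeseries <- function(group, config, seed) {
  C <- config$coupling_matrices[[group]]
  if (is.null(C)) stop("no coupling matrix for group ", group)
  set.seed(as.integer(seed))
  T_ <- config$n_frames
  n <- config$n_networks
  k <- config$voxels_per_network
  L <- matrix(rnorm(T_ * n), T_, n) %*% chol(C)
  colnames(L) <- config$networks
  blocks <- lapply(seq_len(n), function(i) {
    L[, i] + matrix(rnorm(T_ * k, sd = config$noise_sd), T_, k)
  })
  names(blocks) <- config$networks
  structure(list(frames = T_, blocks = blocks, latents = L),
            class = "timeseries_set")
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subjects with group sizes matching `group_proportions`
#' (largest-remainder rounding), group-dependent demographics, contralesional
#' cortical thickness, class-consistent truncated-lognormal survival times,
#' and one BOLD time-series set per subject.  The same configuration and seed
#' reproduce the cohort exactly.
#'
#' @param config A [sim_config()].
#' @param timeseries Generate BOLD matrices (default `TRUE`); set `FALSE`
#'   for demographics-only cohorts.
#' @return Object of class `gbm_cohort`: `subjects` (data frame with
#'   `subject_id`, `age`, `sex`, `ct_01..ct_34`, `survival_months`, `event`,
#'   `survival_class`), `timeseries` (named list of `timeseries_set`), and
#'   the generating `config`.
#' @export
generate_cohort <- function(config, timeseries = TRUE) {
  validate_sim_config(config)
  classes <- survival_classes()
  sizes <- allocate_groups(config$n_subjects, config$group_proportions)
  group <- factor(rep(classes, sizes), levels = classes)
  n <- config$n_subjects
  seeds <- derive_seeds(config$seed, 2L + n)
  set.seed(seeds[1L])

  gi <- as.integer(group)
  age <- rnorm(n, mean = config$age_mean_by_group[gi], sd = config$age_sd)
  age <- pmax(age, 18)
  sex <- rbinom(n, 1L, config$sex_prob_by_group[gi])
  ct <- matrix(rep(config$ct_baseline, each = n), n, 34) +
    config$ct_group_shift[gi] +
    matrix(rnorm(n * 34, sd = config$ct_noise_sd), n, 34)
  ct <- pmax(ct, 0.5)  # cortex never vanishes
  colnames(ct) <- sprintf("ct_%02d", 1:34)

  intervals <- list(c(0, 12), c(12, 24), c(24, Inf))
  months <- numeric(n)
  for (g in seq_len(3L)) {
    sel <- gi == g
    if (any(sel)) {
      months[sel] <- draw_survival(sum(sel),
                                   config$survival_scale_by_group[g],
                                   config$survival_sdlog, intervals[[g]])
    }
  }
  event <- 1L - rbinom(n, 1L, config$censor_rate)

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, sex = sex, ct,
    survival_months = months, event = event,
    survival_class = group,
    stringsAsFactors = FALSE
  )

  ts <- NULL
  if (timeseries && n > 0) {
    ts <- lapply(seq_len(n), function(i) {
      generate_timeseries(as.character(group[i]), config, seeds[2L + i])
    })
    names(ts) <- subjects$subject_id
  }
  structure(list(subjects = subjects, timeseries = ts, config = config),
            class = "gbm_cohort")
}

#' @export
print.gbm_cohort <- function(x, ...) {
  cat("Synthetic GBM cohort:", nrow(x$subjects), "subjects\n")
  print(table(x$subjects$survival_class))
  if (!is.null(x$timeseries)) {
    ts <- x$timeseries[[1L]]
    cat("BOLD:", ts$frames, "frames x", length(ts$blocks), "networks x",
        ncol(ts$blocks[[1L]]), "voxels\n")
  }
  invisible(x)
}

#' Generate per-network voxel probability maps
#'
#' Builds one synthetic voxelwise probability map per network over a common
#' one-dimensional voxel grid, standing in for published resting-state
#' network probability maps.  Each network receives a contiguous support
#' (disjoint across networks) with uniform-random probabilities in (0, 1];
#' every map has at least `voxels_per_network` strictly positive entries so
#' that top-k ROI selection is well defined.
#'
#' @param config A [sim_config()].
#' @param grid_size Total number of voxels in the common grid; default
#'   `ceiling(1.25 * n_networks * voxels_per_network)`.
#' @return List of `probability_map` objects (`network`, `values`).
#' @export
generate_probability_maps <- function(config, grid_size = NULL) {
  n <- config$n_networks
  k <- config$voxels_per_network
  if (is.null(grid_size)) grid_size <- ceiling(1.25 * n * k)
  if (grid_size < n * k) {
    stop("configuration error: grid of ", grid_size,
         " voxels cannot host ", n, " networks of ", k, " voxels")
  }
  seeds <- derive_seeds(config$seed, 1L)
  set.seed(seeds[1L])
  support <- floor(grid_size / n)
  maps <- lapply(seq_len(n), function(i) {
    values <- numeric(grid_size)
    idx <- ((i - 1L) * support + 1L):(i * support)
    values[idx] <- runif(length(idx), min = .Machine$double.eps, max = 1)
    structure(list(network = config$networks[i], values = values),
              class = "probability_map")
  })
  names(maps) <- config$networks
  maps
}
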
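#' Canonical resting-state network codes
#'
#' The 15 resting-state networks (RSNs) used throughout the package, in the
#' canonical order that fixes the layout of the 120-element connectome vector:
#' dorsal somatomotor (SMD), inferior somatomotor (SMI), cinguloopercular
#' (CON), auditory (AUD), default mode (DMN), parietal memory (PMN), visual
#' (VIS), frontoparietal (FPN), salience (SAL), ventral attention (VAN),
#' dorsal attention (DAN), medial temporal (MET), reward (REW), thalamus
#' (THA), basal ganglia (BGA).
#'
#' @return Character vector of the 15 network codes.
#' @export
canonical_networks <- function() {
  c("SMD", "SMI", "CON", "AUD", "DMN", "PMN", "VIS", "FPN",
    "SAL", "VAN", "DAN", "MET", "REW", "THA", "BGA")
}

#' Connectome pair labels
#'
#' Labels for all unordered network pairs (self-pairs included) in
#' upper-triangle row-major order over `networks`; for the 15 canonical
#' networks this yields the 120 labels `SMDxSMD, SMDxSMI, ..., BGAxBGA`.
#'
#' @param networks Character vector of network codes (default canonical 15).
#' @return Character vector of length `n(n+1)/2` with labels `"AxB"`.
#' @export
fc_pair_labels <- function(networks = canonical_networks()) {
  n <- length(networks)
  labs <- character(n * (n + 1L) / 2L)
  idx <- 1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      labs[idx] <- paste0(networks[i], "x", networks[j])
      idx <- idx + 1L
    }
  }
  labs
}

# Split "AxB" labels into a 2-column character matrix.
parse_pair_labels <- function(labels) {
  parts <- strsplit(labels, "x", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed pair label(s): ", paste(labels[bad], collapse = ", "))
  }
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

#' Desikan-Killiany cortical parcels
#'
#' Names of the 34 Desikan-Killiany cortical parcels, in the order of the
#' `ct_01..ct_34` columns of cohort tables.  Cortical thickness is measured
#' on the hemisphere contralateral to the tumor.
#'
#' @return Character vector of 34 parcel names.
#' @export
dk_parcels <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal", "frontalpole", "insula")
}

#' Survival class labels
#'
#' The three overall-survival classes: death before 12 months (`LT1Y`),
#' between 12 and 24 months inclusive (`Y1TO2`), after 24 months (`GT2Y`).
#'
#' @return Character vector of the three class codes, worst prognosis first.
#' @export
survival_classes <- function() c("LT1Y", "Y1TO2", "GT2Y")

#' Classify a survival time in months
#'
#' Maps survival times onto the three classes with closed boundaries at 12
#' and 24 months: exactly 12 or 24 months falls in `Y1TO2`.
#'
#' @param months Numeric vector of positive survival times in months.
#' @return Factor with levels `LT1Y`, `Y1TO2`, `GT2Y`.
#' @export
classify_survival <- function(months) {
  if (any(!is.finite(months)) || any(months <= 0)) {
    stop("survival times must be positive and finite")
  }
  cls <- ifelse(months < 12, "LT1Y", ifelse(months <= 24, "Y1TO2", "GT2Y"))
  factor(cls, levels = survival_classes())
}

# Derive reproducible sub-seeds from a master seed; keeps every seed a
# valid 32-bit integer.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
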
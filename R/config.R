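# Binning / labeling configuration: fully determines key values.

#' @keywords internal
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Residue-identity labels for CA mode: the 20 standard residues numbered
# alphabetically by three-letter code.
aa_label_map <- function() {
  stats::setNames(seq_along(STANDARD_AA), STANDARD_AA)
}

# Element labels for COFACTOR/AA modes.  Organic and cofactor-relevant
# elements first; anything else must be added explicitly via `label_map`.
element_label_map <- function() {
  c(C = 1L, N = 2L, O = 3L, S = 4L, MG = 5L, P = 6L, FE = 7L)
}

#' Default amino-acid grouping map
#'
#' Residues with similar structure and chemistry are merged to one label
#' before vertex ordering: (ASP,GLU), (ASN,GLN), (SER,THR), (LYS,ARG),
#' (ILE,LEU,VAL), (PHE,TYR,TRP).  Each group maps to its alphabetically
#' first member.  Used by the grouping variant of the backbone key mode.
#'
#' @return Named character vector mapping residue code to group
#'   representative; residues absent from the map are left unchanged.
#' @export
aa_grouping_map <- function() {
  c(GLU = "ASP", GLN = "ASN", THR = "SER", ARG = "LYS",
    LEU = "ILE", VAL = "ILE", TYR = "PHE", TRP = "PHE")
}

#' Atom-name presets for [filter_atoms()]
#'
#' `"phytol_tail"` is the chlorophyll tail-carbon set C6..C20, used to
#' restrict cofactor keys to the chlorin ring.
#'
#' @param name Preset name.
#' @return Character vector of atom names to exclude.
#' @export
atom_filter_preset <- function(name = "phytol_tail") {
  presets <- list(phytol_tail = paste0("C", 6:20))
  if (!name %in% names(presets)) {
    stop("unknown atom filter preset: ", name, call. = FALSE)
  }
  presets[[name]]
}

#' Construct a key-generation configuration
#'
#' A configuration fixes the vertex label map, the Theta and MaxDist bin
#' boundaries and the optional size-gap cutoff and label grouping; two key
#' vectors are comparable only under the same configuration (checked via
#' its hash).
#'
#' Defaults per mode:
#' * `CA`: residue-identity labels (m = 20), 35 MaxDist bins of 3 Angstrom
#'   over (0, 105].
#' * `COFACTOR`: element labels, 17 MaxDist bins of 1 Angstrom.
#' * `AA`: element labels, 58 MaxDist bins of 1 Angstrom.
#'
#' All modes default to 30 equal-width Theta bins over (0, 90] degrees.
#' MaxDist beyond the last boundary falls in the last bin; Theta of
#' exactly 90 degrees falls in the last Theta bin.
#'
#' @param mode One of `"CA"`, `"COFACTOR"`, `"AA"`.
#' @param theta_bins Increasing upper bin boundaries in degrees.
#' @param dist_bins Increasing upper bin boundaries in Angstrom.
#' @param label_map Named integer vector label -> positive integer.
#' @param size_gap_cutoff Optional MaxDist cutoff in Angstrom; triangles
#'   with a longer longest edge are dropped (size-gap filter).
#' @param grouping_map Optional named character vector merging labels
#'   (e.g. [aa_grouping_map()]) applied before label lookup.
#' @return An object of class `tsr_config`.
#' @export
tsr_config <- function(mode = c("CA", "COFACTOR", "AA"),
                       theta_bins = NULL, dist_bins = NULL,
                       label_map = NULL, size_gap_cutoff = NULL,
                       grouping_map = NULL) {
  mode <- match.arg(mode)
  if (is.null(theta_bins)) theta_bins <- seq(3, 90, by = 3)
  if (is.null(dist_bins)) {
    dist_bins <- switch(mode,
      CA = seq(3, 105, by = 3),
      COFACTOR = seq_len(17),
      AA = seq_len(58))
  }
  if (is.null(label_map)) {
    label_map <- switch(mode, CA = aa_label_map(), element_label_map())
  }
  stopifnot(length(theta_bins) >= 1, length(dist_bins) >= 1)
  if (any(diff(theta_bins) <= 0) || any(diff(dist_bins) <= 0)) {
    stop("bin boundaries must be strictly increasing", call. = FALSE)
  }
  lm <- as.integer(label_map)
  names(lm) <- names(label_map)
  if (anyDuplicated(lm) || any(lm < 1L)) {
    stop("label_map must assign distinct positive integers", call. = FALSE)
  }
  if (!is.null(size_gap_cutoff)) {
    stopifnot(is.numeric(size_gap_cutoff), size_gap_cutoff > 0)
  }
  cfg <- structure(list(
    mode = mode,
    label_map = lm,
    m = max(lm),
    theta_bins = as.numeric(theta_bins),
    dist_bins = as.numeric(dist_bins),
    n_theta = length(theta_bins),
    n_dist = length(dist_bins),
    size_gap_cutoff = size_gap_cutoff,
    grouping_map = grouping_map
  ), class = "tsr_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  rlang::hash(list(cfg$mode, cfg$label_map, cfg$theta_bins, cfg$dist_bins,
                   cfg$size_gap_cutoff, cfg$grouping_map))
}

#' @export
print.tsr_config <- function(x, ...) {
  cat("tsr_config [", x$mode, "]  m=", x$m,
      "  theta bins=", x$n_theta,
      "  dist bins=", x$n_dist,
      if (!is.null(x$size_gap_cutoff))
        paste0("  size-gap cutoff=", x$size_gap_cutoff, " A"),
      "\n  hash: ", x$hash, "\n", sep = "")
  invisible(x)
}

# Assign a bin index for values against upper boundaries; values above the
# last boundary land in the last bin, values at or below the first in bin 1.
bin_index <- function(x, bounds) {
  i <- findInterval(x, bounds, left.open = TRUE) + 1L
  pmin(i, length(bounds))
}
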
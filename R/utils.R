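# Internal helpers shared across modules.

# Derive independent child seeds from one user-facing seed, so that every
# random stage of a run descends from a single integer without sharing a
# stream. Values stay below 2^31 - 1 (R integers).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Region-name vector for the 68-region Desikan-Killiany gyral parcellation
# (34 per hemisphere), the standard node set for cortical-thickness
# covariance networks.

#' Desikan-Killiany region names
#'
#' Returns the 68 gyral region labels (34 per hemisphere, prefixed `lh_` /
#' `rh_`) of the Desikan-Killiany cortical parcellation, the default node
#' set for structural covariance networks built from cortical thickness.
#'
#' @return Character vector of length 68.
#' @export
#' @examples
#' head(dk68_regions())
dk68_regions <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal", "frontalpole", "insula"
  )
  c(paste0("lh_", base), paste0("rh_", base))
}

# Column names of a cohort tibble that hold region values (everything that
# is not the subject/group identifier).
region_columns <- function(cohort, group_col = "group", subject_col = "subject") {
  setdiff(names(cohort), c(subject_col, group_col))
}

# Extract the subject x region numeric matrix for one group.
group_values <- function(cohort, group, group_col = "group",
                         subject_col = "subject") {
  regions <- region_columns(cohort, group_col, subject_col)
  rows <- cohort[[group_col]] == group
  if (!any(rows)) {
    abort(sprintf("group '%s' not present in cohort", group))
  }
  m <- as.matrix(cohort[rows, regions, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cohort[[subject_col]][rows]
  m
}

# Group labels in order of first appearance; the first is "group A" in all
# A-minus-B difference statistics.
group_levels <- function(cohort, group_col = "group") {
  unique(as.character(cohort[[group_col]]))
}

# Trapezoidal AUC over a density grid, dropping non-finite values pairwise
# with a companion vector (both profiles must be defined at a density for it
# to contribute to either integral).
auc_trapezoid <- function(x, y, drop_with = NULL) {
  keep <- is.finite(y)
  if (!is.null(drop_with)) keep <- keep & is.finite(drop_with)
  if (sum(keep) < 2L) {
    warn("fewer than two defined grid points; AUC set to 0")
    return(0)
  }
  pracma::trapz(x[keep], y[keep])
}
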
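# loaders for the editable chemistry tables shipped under inst/extdata

load_yaml_cached <- function(key, path) {
  if (is.null(.sift2d_cache[[key]])) {
    .sift2d_cache[[key]] <- yaml::read_yaml(path)
  }
  .sift2d_cache[[key]]
}

#' Residue class membership table
#'
#' Returns the five interaction-capability classes (aromatic, hydrophobic,
#' polar, negatively_charged, positively_charged) as a named list of
#' 3-letter-code vectors, plus a `aliases` map for protonation variants.
#'
#' @param path optional path to a user-supplied YAML table with the same keys.
#' @return named list of character vectors.
#' @export
residue_class_table <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  load_yaml_cached("classes", sift2d_extdata("residue_classes.yaml"))
}

residue_atom_table <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  load_yaml_cached("atoms", sift2d_extdata("residue_atoms.yaml"))
}

#' Default incrementable-cell mask
#'
#' A 7x9 logical matrix marking which (feature row, interaction column) cells
#' of a residue block may be incremented; all other cells are structurally
#' zero. Rows follow the canonical feature order A, D, H, N, P, R, vdW and
#' columns the interaction order Any, BB, SC, P, H, A, D, C, R.
#'
#' @param path optional CSV with columns `feature,Any,...,R` overriding the
#'   shipped default.
#' @return logical matrix with feature rownames and interaction colnames.
#' @export
increment_mask <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sift2d_cache$mask)) return(.sift2d_cache$mask)
    path <- sift2d_extdata("increment_mask.csv")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, INTERACTION_TYPES]) > 0
  rownames(m) <- tab$feature
  m <- m[FEATURE_TYPES, INTERACTION_TYPES]
  if (cache) .sift2d_cache$mask <- m
  m
}

# backbone atom names (hydrogens attached to these are backbone too)
BACKBONE_HEAVY <- c("N", "CA", "C", "O", "OXT")
BACKBONE_H <- c("H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HXT")

# single-bond covalent radii (Angstrom) for distance-based bond perception
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Se = 1.20
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")
ION_NAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "BR",
               "IOD", "CD", "NI", "CO", "HG", "SO4", "PO4")
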
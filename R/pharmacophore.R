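# SMARTS-based assignment of the seven ligand pharmacophore feature rows.

FEATURE_DEF_KEYS <- c(acceptor = "A", donor = "D", hydrophobic = "H",
                      negative = "N", positive = "P", aromatic = "R")

#' Read a pharmacophore feature-definition file
#'
#' YAML mapping the six explicit feature types (acceptor, donor, hydrophobic,
#' negative, positive, aromatic) to named SMARTS patterns; see the shipped
#' `features.yaml` for the format. The seventh row (vdW) needs no pattern:
#' every ligand heavy atom carries it.
#'
#' @param path optional path to a user feature file; default ships with the
#'   package.
#' @return the parsed definition list.
#' @export
read_feature_defs <- function(path = NULL) {
  if (is.null(path)) {
    return(load_yaml_cached("features", sift2d_extdata("features.yaml")))
  }
  defs <- yaml::read_yaml(path)
  missing <- setdiff(names(FEATURE_DEF_KEYS), names(defs))
  if (length(missing)) {
    stop("feature-definition file lacks types: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  defs
}

#' Assign pharmacophore features to a ligand
#'
#' Matches the SMARTS patterns of each feature type against the ligand
#' (OpenBabel engine), merges matches with identical atom sets, absorbs
#' matches fully contained in a larger match of the same type, clusters
#' contiguous hydrophobic atoms into one feature per apolar fragment, and
#' computes feature geometry: centroid = unweighted mean of the member heavy
#' atoms; aromatic features additionally carry the best-fit ring plane
#' normal. Hydrogens are never feature members; ligand donors acquire their
#' hydrogens later, during interaction evaluation.
#'
#' @param ligand a `sift2d_ligand` from [parse_complex()].
#' @param smarts_defs optional path to a feature-definition file, or a parsed
#'   definition list.
#' @return list of features (class `sift2d_features`), each with `type`,
#'   `atom_indices`, `centroid`, `ring_normal` (aromatic only), `feature_id`
#'   (dense from 0).
#' @export
assign_features <- function(ligand, smarts_defs = NULL) {
  defs <- if (is.character(smarts_defs)) read_feature_defs(smarts_defs)
          else if (is.list(smarts_defs)) smarts_defs
          else read_feature_defs()
  mol <- ob_read(ligand$block_text, ligand$block_format)
  heavy_idx <- which(!ligand$atoms$is_h)

  features <- list()
  for (def_name in names(FEATURE_DEF_KEYS)) {
    type <- FEATURE_DEF_KEYS[[def_name]]
    spec <- defs[[def_name]]
    if (is.null(spec)) next
    sets <- list()
    for (pat in spec$patterns) {
      matches <- ob_smarts_match(mol, pat$smarts)
      for (m in matches) {
        if (!is.null(pat$members)) m <- m[pat$members]
        m <- sort(unique(m[!ligand$atoms$is_h[m]]))
        if (length(m)) sets <- c(sets, list(m))
      }
    }
    sets <- unique(sets)
    # absorb matches that are strict subsets of another match of this type
    if (length(sets) > 1L) {
      keep <- vapply(seq_along(sets), function(i) {
        !any(vapply(seq_along(sets), function(j) {
          i != j && length(sets[[i]]) <= length(sets[[j]]) &&
            all(sets[[i]] %in% sets[[j]]) &&
            !identical(sets[[i]], sets[[j]])
        }, logical(1)))
      }, logical(1))
      sets <- sets[keep]
    }
    if (isTRUE(spec$cluster) && length(sets)) {
      sets <- cluster_atom_sets(unlist(sets), ligand$bonds)
    }
    for (m in sets) {
      f <- list(type = type, atom_indices = m,
                centroid = colMeans(coord_matrix(ligand$atoms[m, ])),
                ring_normal = NULL)
      if (type == "R") {
        geom <- ring_geometry(list(type = "R",
                                   coords = coord_matrix(ligand$atoms[m, ])))
        f$centroid <- geom$centroid
        f$ring_normal <- geom$normal
      }
      features <- c(features, list(f))
    }
  }

  # canonical order: feature type row order, then first member atom
  ord <- order(match(vapply(features, `[[`, "", "type"), FEATURE_TYPES),
               vapply(features, function(f) f$atom_indices[1L], integer(1)))
  features <- features[ord]
  for (i in seq_along(features)) features[[i]]$feature_id <- i - 1L
  structure(features, class = "sift2d_features",
            heavy_atoms = heavy_idx)
}

# connected components of matched atoms under the ligand bond graph
cluster_atom_sets <- function(atoms, bonds) {
  atoms <- sort(unique(atoms))
  comp <- seq_along(atoms)
  names(comp) <- atoms
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  b <- bonds[bonds$a1 %in% atoms & bonds$a2 %in% atoms, , drop = FALSE]
  for (k in seq_len(nrow(b))) {
    i <- find(match(b$a1[k], atoms))
    j <- find(match(b$a2[k], atoms))
    if (i != j) comp[j] <- i
  }
  roots <- vapply(seq_along(atoms), find, integer(1))
  unname(lapply(split(atoms, roots), as.integer))
}

#' Centroid and plane normal of an aromatic feature
#'
#' The normal is the unit vector minimizing squared out-of-plane deviation
#' (smallest principal axis of the member coordinates). Its sign is
#' arbitrary; all angle comparisons in the package fold angles to
#' `[0, 90]` degrees.
#'
#' @param feature a feature with `coords` (matrix) or, as produced by
#'   [assign_features()], `centroid`/`ring_normal` already set.
#' @return list with `centroid` and unit `normal`.
#' @export
ring_geometry <- function(feature) {
  if (!is.null(feature$coords)) {
    fit <- best_fit_plane(feature$coords)
    return(fit)
  }
  list(centroid = feature$centroid, normal = feature$ring_normal)
}

# coordinates of hydrogens bonded to a ligand heavy atom
ligand_donor_hs <- function(ligand, atom_idx) {
  b <- ligand$bonds
  partners <- c(b$a2[b$a1 == atom_idx], b$a1[b$a2 == atom_idx])
  hs <- partners[ligand$atoms$is_h[partners]]
  if (length(hs) == 0L) {
    # fall back to a covalent distance criterion
    xyz <- coord_matrix(ligand$atoms)
    d <- sqrt(colSums((t(xyz) - xyz[atom_idx, ])^2))
    hs <- which(ligand$atoms$is_h & d <= 1.3 & d > 0)
  }
  coord_matrix(ligand$atoms[hs, , drop = FALSE])
}

#' @export
print.sift2d_features <- function(x, ...) {
  types <- vapply(x, `[[`, "", "type")
  cat("<sift2d features: ", length(x), " (",
      paste(sprintf("%s=%d", FEATURE_TYPES[1:6],
                    vapply(FEATURE_TYPES[1:6], function(t) sum(types == t),
                           integer(1))), collapse = " "),
      ")>\n", sep = "")
  invisible(x)
}
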
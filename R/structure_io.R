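# Parsing of protein-ligand complexes and residue-level annotation.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

normalize_resname <- function(name, table = NULL) {
  tab <- if (is.null(table)) residue_class_table() else table
  ali <- tab$aliases
  ifelse(name %in% names(ali), unlist(ali)[name], name)
}

#' Classify a residue into interaction-capability classes
#'
#' Membership follows the shipped class table (see [residue_class_table()]):
#' e.g. PHE is aromatic and hydrophobic, TYR aromatic and polar, HIS aromatic,
#' polar and positively charged. Charged residues (ASP, GLU, LYS, ARG) are not
#' additionally listed as polar: their contacts are captured by the dedicated
#' charged detector. Protonation-variant names (HID/HIE/HIP, ...) are mapped
#' to their parent residue first.
#'
#' @param name 3-letter residue code.
#' @param table optional class table (list as returned by
#'   [residue_class_table()]) overriding the default.
#' @return character vector of classes, possibly empty (with a warning for
#'   names outside the table).
#' @examples
#' classify_residue("PHE")
#' classify_residue("ASP")
#' @export
classify_residue <- function(name, table = NULL) {
  tab <- if (is.null(table)) residue_class_table() else table
  key <- normalize_resname(name, tab)
  classes <- RESIDUE_CLASSES[vapply(RESIDUE_CLASSES,
                                    function(cl) key %in% tab[[cl]],
                                    logical(1))]
  if (length(classes) == 0L && !(key %in% STANDARD_AA)) {
    warning("unknown residue name '", name,
            "': no interaction classes assigned (still counts for vdW contacts)",
            call. = FALSE)
  }
  unname(classes)
}

#' Partition residue atoms into backbone and side chain
#'
#' Backbone is N, CA, C, O, OXT plus hydrogens bonded to them (bonding by a
#' 1.3 Angstrom distance criterion, falling back to standard H names). All
#' remaining atoms are side chain; for GLY the side chain has no heavy atoms.
#'
#' @param residue a residue object from [parse_complex()].
#' @return the residue with its `atoms$region` column filled ("bb"/"sc").
#' @export
split_backbone_sidechain <- function(residue) {
  at <- residue$atoms
  region <- ifelse(at$name %in% BACKBONE_HEAVY, "bb", "sc")
  heavy <- !at$is_h
  if (any(at$is_h)) {
    hxyz <- coord_matrix(at[at$is_h, ])
    if (any(heavy)) {
      xyz <- coord_matrix(at[heavy, ])
      hreg <- region[heavy][apply(hxyz, 1L, function(h) {
        which.min(colSums((t(xyz) - h)^2))
      })]
      dmin <- apply(hxyz, 1L, function(h) sqrt(min(colSums((t(xyz) - h)^2))))
      # hydrogens not within covalent range of any heavy atom: fall back to names
      far <- dmin > 1.3
      hreg[far] <- ifelse(at$name[at$is_h][far] %in% BACKBONE_H, "bb", "sc")
      region[at$is_h] <- hreg
    }
  }
  residue$atoms$region <- region
  residue
}

new_residue <- function(chain, seqnum, icode, name, atoms, class_table = NULL) {
  r <- structure(
    list(chain = chain, seqnum = as.integer(seqnum), insertion_code = icode,
         name = name, atoms = atoms, generic_number = NA_character_,
         classes = classify_residue(name, class_table)),
    class = "sift2d_residue")
  split_backbone_sidechain(r)
}

residue_key <- function(residue) {
  paste0(residue$chain, "/", residue$seqnum,
         ifelse(nzchar(residue$insertion_code), residue$insertion_code, ""))
}

# coordinates of selected residue atoms as a matrix (possibly 0-row)
residue_coords <- function(residue, heavy = TRUE, region = NULL, names = NULL,
                           elements = NULL) {
  at <- residue$atoms
  keep <- rep(TRUE, nrow(at))
  if (heavy) keep <- keep & !at$is_h
  if (!is.null(region)) keep <- keep & at$region %in% region
  if (!is.null(names)) keep <- keep & at$name %in% names
  if (!is.null(elements)) keep <- keep & at$element %in% elements
  coord_matrix(at[keep, , drop = FALSE])
}

element_from_pdb <- function(elesy, name) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | !nzchar(el)
  if (any(bad)) {
    # derive from the atom name: first alphabetic character(s)
    guess <- sub("^[0-9]*", "", name[bad])
    el[bad] <- ifelse(substr(guess, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
                      substr(guess, 1, 1), substr(guess, 1, 1))
  }
  el <- ifelse(nchar(el) == 2, paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
  el
}

# keep only the highest-occupancy alternate location per atom
filter_altloc <- function(atoms) {
  if (all(atoms$alt %in% c("", " ", NA))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety)
  occ <- ifelse(is.na(atoms$o), 1, atoms$o)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    alt <- atoms$alt[idx]
    if (length(unique(atoms$elety[idx])) < length(idx)) {
      idx[order(-occ[idx], alt)][1L]
    } else idx
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

atoms_tibble <- function(name, element, x, y, z, charge = 0L) {
  tibble::tibble(
    name = name, element = element,
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    is_h = element == "H", charge = as.integer(charge),
    region = NA_character_)
}

#' Parse a protein-ligand complex
#'
#' Reads a PDB text block (hydrogens expected for full hydrogen-bond
#' geometry; a warning is issued and distance-only detection used when they
#' are absent). The ligand comes either from a separate SDF/MOL V2000 block
#' (`ligand_block`) or from HETATM records selected by residue name
#' (`ligand_selector`). Waters and common ions are excluded from both sides.
#' Alternate locations keep the highest-occupancy conformer only.
#'
#' @param pdb_text character vector (lines) or single string of PDB text.
#' @param ligand_block optional SDF/MOL V2000 text for the ligand.
#' @param ligand_selector optional HETATM residue name identifying the ligand;
#'   when both are `NULL` a single non-water HETATM residue is auto-selected.
#' @param identifier complex identifier stored in the result.
#' @param class_table optional residue class table override.
#' @return a `sift2d_complex`: ordered residues, ligand, identifier.
#' @export
parse_complex <- function(pdb_text, ligand_block = NULL, ligand_selector = NULL,
                          identifier = "complex", class_table = NULL) {
  if (length(pdb_text) == 1L) pdb_text <- strsplit(pdb_text, "\n")[[1]]
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(pdb_text, tmp)
  pdb <- tryCatch(bio3d::read.pdb(tmp, verbose = FALSE),
                  error = function(e) {
                    stop("format error: unparseable PDB text (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- filter_altloc(at)
  at$element <- element_from_pdb(at$elesy, at$elety)
  drop <- at$resid %in% WATER_NAMES |
    (at$type == "HETATM" & at$resid %in% ION_NAMES)
  at <- at[!drop, , drop = FALSE]

  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) {
    stop("format error: no protein ATOM records found", call. = FALSE)
  }
  rid <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  ord <- order(prot$chain, prot$resno, prot$insert)
  rid_levels <- unique(rid[ord])
  residues <- lapply(rid_levels, function(k) {
    rows <- prot[rid == k, , drop = FALSE]
    new_residue(rows$chain[1L], rows$resno[1L], rows$insert[1L],
                rows$resid[1L],
                atoms_tibble(rows$elety, rows$element, rows$x, rows$y, rows$z),
                class_table)
  })

  ligand <- parse_ligand(ligand_block, ligand_selector,
                         at[at$type == "HETATM", , drop = FALSE])

  n_polar_h <- sum(vapply(residues, function(r) {
    sum(r$atoms$is_h & r$atoms$region == "sc") + sum(r$atoms$name == "H")
  }, numeric(1)))
  degraded <- n_polar_h == 0L
  if (degraded) {
    warning("no hydrogens found on the protein: hydrogen bonds will be ",
            "detected by heavy-atom distance only", call. = FALSE)
  }

  structure(list(residues = residues, ligand = ligand,
                 identifier = identifier, hydrogens_present = !degraded),
            class = "sift2d_complex")
}

parse_ligand <- function(ligand_block, ligand_selector, het) {
  if (!is.null(ligand_block)) return(parse_mol_ligand(ligand_block))
  if (nrow(het) == 0L) {
    stop("ligand-missing: no HETATM records and no ligand block supplied",
         call. = FALSE)
  }
  rid <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  if (is.null(ligand_selector)) {
    cand <- unique(het$resid)
    if (length(cand) > 1L) {
      stop("ligand-ambiguous: multiple HETATM residues (",
           paste(cand, collapse = ", "),
           "); supply ligand_selector", call. = FALSE)
    }
    ligand_selector <- cand
  }
  sel <- het[het$resid == ligand_selector, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("ligand-missing: no HETATM residue named '", ligand_selector, "'",
         call. = FALSE)
  }
  if (length(unique(rid[het$resid == ligand_selector])) > 1L) {
    stop("ligand-ambiguous: selector '", ligand_selector,
         "' matches more than one residue instance", call. = FALSE)
  }
  atoms <- atoms_tibble(sel$elety, sel$element, sel$x, sel$y, sel$z)
  atoms$region <- "lig"
  bonds <- perceive_bonds(atoms)
  pdb_lines <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), substr(atoms$name, 1, 4), ligand_selector,
    ifelse(is.na(sel$chain) | !nzchar(sel$chain), "A", sel$chain)[1L],
    sel$resno[1L], atoms$x, atoms$y, atoms$z, toupper(atoms$element))
  structure(list(atoms = atoms, bonds = bonds, source_format = "pdb_het",
                 block_text = c(pdb_lines, "END"), block_format = "pdb"),
            class = "sift2d_ligand")
}

parse_mol_ligand <- function(ligand_block) {
  if (length(ligand_block) == 1L) ligand_block <- strsplit(ligand_block, "\n")[[1]]
  if (!any(grepl("\\$\\$\\$\\$", ligand_block))) {
    ligand_block <- c(ligand_block, "$$$$")
  }
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(ligand_block, tmp)
  sdf <- tryCatch(ChemmineR::read.SDFset(tmp),
                  error = function(e) {
                    stop("format error: unparseable MOL/SDF block (",
                         conditionMessage(e), ")", call. = FALSE)
                  })[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  mol <- ob_read(ligand_block, "sdf")
  charge <- ob_formal_charges(mol)
  atoms <- atoms_tibble(rownames(ab), element, ab[, 1L], ab[, 2L], ab[, 3L],
                        charge)
  atoms$region <- "lig"
  if (all(abs(atoms$z) < 1e-9) && all(abs(atoms$y) < 1e-9)) {
    warning("ligand block appears to lack 3D coordinates", call. = FALSE)
  }
  bonds <- tibble::tibble(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                          order = as.integer(bb[, 3L]))
  if (any(bonds$a1 > nrow(atoms) | bonds$a2 > nrow(atoms))) {
    stop("format error: bond indices out of range in ligand block",
         call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds, source_format = "sdf",
                 block_text = ligand_block, block_format = "sdf"),
            class = "sift2d_ligand")
}

# covalent-radius bond perception for PDB-only ligands
perceive_bonds <- function(atoms, slack = 0.45) {
  n <- nrow(atoms)
  if (n < 2L) return(tibble::tibble(a1 = integer(), a2 = integer(),
                                    order = integer()))
  xyz <- coord_matrix(atoms)
  r <- COVALENT_RADII[atoms$element]
  r[is.na(r)] <- 0.77
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[pairs[, 1L], , drop = FALSE] -
                       xyz[pairs[, 2L], , drop = FALSE])^2))
  cutoff <- r[pairs[, 1L]] + r[pairs[, 2L]] + slack
  hh <- atoms$is_h[pairs[, 1L]] & atoms$is_h[pairs[, 2L]]
  keep <- d <= cutoff & d > 0.4 & !hh
  tibble::tibble(a1 = pairs[keep, 1L], a2 = pairs[keep, 2L], order = 1L)
}

#' Read a generic-residue-number annotation table
#'
#' A 3-column CSV `chain,seqnum,generic_number`. Ballesteros-Weinstein style
#' labels ("3.32") are normalized to GPCRdb style ("3x32") textually; any
#' positional renumbering between the two schemes must already be encoded in
#' the table.
#'
#' @param path CSV file path.
#' @return tibble with columns chain, seqnum, generic_number.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("character", "integer",
                                              "character"))
  names(tab) <- c("chain", "seqnum", "generic_number")
  tibble::as_tibble(tab)
}

normalize_generic <- function(x) sub("\\.", "x", x)

#' Attach generic residue numbers to a complex
#'
#' @param complex a `sift2d_complex`.
#' @param annotation data frame with columns chain, seqnum, generic_number
#'   (e.g. from [read_annotation()]). Keys must be unique.
#' @return the complex with matching residues labeled; annotation rows that
#'   match no residue produce a warning and are ignored.
#' @export
attach_generic_numbers <- function(complex, annotation) {
  if (nrow(annotation) == 0L) return(complex)
  key <- paste(annotation$chain, annotation$seqnum)
  if (anyDuplicated(key)) {
    stop("annotation keys (chain, seqnum) must be unique", call. = FALSE)
  }
  gn <- setNames(normalize_generic(annotation$generic_number), key)
  seen <- setNames(rep(FALSE, length(gn)), key)
  complex$residues <- lapply(complex$residues, function(r) {
    k <- paste(r$chain, r$seqnum)
    if (k %in% names(gn)) {
      r$generic_number <- unname(gn[[k]])
      seen[[k]] <<- TRUE
    }
    r
  })
  if (any(!seen)) {
    warning("annotation rows matching no residue ignored: ",
            paste(names(seen)[!seen], collapse = "; "), call. = FALSE)
  }
  complex
}

#' @export
print.sift2d_complex <- function(x, ...) {
  cat("<sift2d complex '", x$identifier, "': ", length(x$residues),
      " residues, ligand with ", sum(!x$ligand$atoms$is_h),
      " heavy atoms (", x$ligand$source_format, ")>\n", sep = "")
  invisible(x)
}
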
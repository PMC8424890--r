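# Geometric interaction criteria and assembly of the per-residue 7x9 block.

#' Geometric interaction parameters
#'
#' Defaults are the published criteria: 3.5 Angstrom for van der Waals,
#' hydrophobic, charged and polar contacts; hydrogen bonds at most 2.8
#' Angstrom (hydrogen-to-acceptor) with donor angular deviation at most 120
#' degrees and acceptor deviation at most 90 degrees; ring stacking at 4.4
#' (face-to-face, interplanar angle at most 30 degrees) and 5.5 Angstrom
#' (edge-to-face, angle at least 60 degrees); pi-cation at 6.6 Angstrom
#' centroid-to-centroid, distance only. All cutoffs are inclusive, with a
#' `boundary_eps` guard so that rigid-body rounding never flips a detector.
#'
#' `hbond_dist_mode` selects what the 2.8 Angstrom limit is measured
#' between: `"hx"` (default) the donor hydrogen and the acceptor heavy atom,
#' `"heavy"` the two heavy atoms.
#'
#' @param contact_dist,hbond_dist,pi_ff_dist,pi_ef_dist,pi_cation_dist
#'   distance cutoffs in Angstrom.
#' @param hbond_donor_angle_max,hbond_acceptor_angle_max,pi_ff_angle_max,pi_ef_angle_min
#'   angle criteria in degrees.
#' @param hbond_dist_mode "hx" or "heavy".
#' @param boundary_eps inclusive-boundary guard in Angstrom/degrees.
#' @return object of class `sift2d_params`.
#' @export
geometry_params <- function(contact_dist = 3.5,
                            hbond_dist = 2.8,
                            hbond_donor_angle_max = 120,
                            hbond_acceptor_angle_max = 90,
                            pi_ff_dist = 4.4,
                            pi_ef_dist = 5.5,
                            pi_cation_dist = 6.6,
                            pi_ff_angle_max = 30,
                            pi_ef_angle_min = 60,
                            hbond_dist_mode = c("hx", "heavy"),
                            boundary_eps = 1e-6) {
  p <- list(contact_dist = contact_dist, hbond_dist = hbond_dist,
            hbond_donor_angle_max = hbond_donor_angle_max,
            hbond_acceptor_angle_max = hbond_acceptor_angle_max,
            pi_ff_dist = pi_ff_dist, pi_ef_dist = pi_ef_dist,
            pi_cation_dist = pi_cation_dist,
            pi_ff_angle_max = pi_ff_angle_max,
            pi_ef_angle_min = pi_ef_angle_min,
            hbond_dist_mode = match.arg(hbond_dist_mode),
            boundary_eps = boundary_eps)
  dists <- p[grepl("dist$", names(p))]
  if (any(unlist(dists) <= 0)) stop("distance cutoffs must be positive",
                                    call. = FALSE)
  angles <- unlist(p[grepl("angle", names(p))])
  if (any(angles < 0 | angles > 180)) {
    stop("angle criteria must lie in [0, 180] degrees", call. = FALSE)
  }
  structure(p, class = "sift2d_params")
}

le <- function(x, cutoff, eps) x <= cutoff + eps
ge <- function(x, cutoff, eps) x >= cutoff - eps

#' Detect steric (vdW) contact of a coordinate set with a residue
#'
#' @param feature_coords coordinate matrix of ligand heavy atoms.
#' @param residue residue object.
#' @param params [geometry_params()].
#' @return logical flags `any`, `bb`, `sc` (minimum heavy-atom distance
#'   within `contact_dist` against the whole residue / backbone / side chain).
#' @export
detect_contact <- function(feature_coords, residue,
                           params = geometry_params()) {
  eps <- params$boundary_eps
  reg_flag <- function(region) {
    xyz <- residue_coords(residue, region = region)
    nrow(xyz) > 0L &&
      le(min_distance(feature_coords, xyz), params$contact_dist, eps)
  }
  bb <- reg_flag("bb")
  sc <- reg_flag("sc")
  list(any = bb || sc, bb = bb, sc = sc)
}

#' Detect a hydrogen bond
#'
#' Fires when, for some hydrogen H bonded to the donor heavy atom Y and an
#' acceptor heavy atom X: the H...X distance is at most `hbond_dist` (or the
#' Y...X distance in `"heavy"` mode), the donor deviation from linearity
#' `180 - angle(Y, H, X)` is at most `hbond_donor_angle_max`, and the
#' acceptor deviation `180 - angle(H, X, antecedent direction)` is at most
#' `hbond_acceptor_angle_max` (skipped when X has no heavy neighbour). When
#' no hydrogen coordinates are available the check degrades to a heavy-atom
#' distance criterion at `contact_dist`.
#'
#' @param donor_heavy 3-vector, donor heavy atom Y.
#' @param donor_hs matrix of hydrogens bonded to Y (0 rows for degraded mode).
#' @param acceptor_atom 3-vector, acceptor heavy atom X.
#' @param acceptor_antecedents matrix of X's bonded heavy neighbours (may be
#'   NULL / 0 rows).
#' @param params [geometry_params()].
#' @return TRUE/FALSE.
#' @export
detect_hbond <- function(donor_heavy, donor_hs, acceptor_atom,
                         acceptor_antecedents = NULL,
                         params = geometry_params()) {
  eps <- params$boundary_eps
  X <- as.numeric(acceptor_atom)
  Y <- as.numeric(donor_heavy)
  hs <- if (is.null(donor_hs)) matrix(numeric(0), 0, 3) else coord_matrix(donor_hs)
  if (nrow(hs) == 0L) {
    return(le(vnorm(Y - X), params$contact_dist, eps))
  }
  ante <- if (is.null(acceptor_antecedents)) matrix(numeric(0), 0, 3)
          else coord_matrix(acceptor_antecedents)
  for (i in seq_len(nrow(hs))) {
    H <- hs[i, ]
    d <- if (params$hbond_dist_mode == "hx") vnorm(H - X) else vnorm(Y - X)
    if (!le(d, params$hbond_dist, eps)) next
    donor_dev <- 180 - angle_deg(Y, H, X)
    if (!le(donor_dev, params$hbond_donor_angle_max, eps)) next
    if (nrow(ante) > 0L) {
      dirs <- sweep(ante, 2, X)
      mean_dir <- colMeans(dirs / sqrt(rowSums(dirs^2)))
      if (vnorm(mean_dir) > 1e-9) {
        acc_dev <- 180 - angle_deg(H, X, X + mean_dir)
        if (!le(acc_dev, params$hbond_acceptor_angle_max, eps)) next
      }
    }
    return(TRUE)
  }
  FALSE
}

#' Detect a complementary charged contact
#'
#' @param feature ligand feature of type "N" or "P".
#' @param residue residue object; must carry the complementary charge class
#'   (ligand N vs positively charged residue, ligand P vs negatively charged).
#' @param params [geometry_params()].
#' @return TRUE/FALSE (minimum distance between the feature atoms and the
#'   residue's charged-group atoms within `contact_dist`).
#' @export
detect_charged <- function(feature, residue, params = geometry_params()) {
  ligand <- feature$ligand
  needed <- if (feature$type == "N") "positively_charged" else "negatively_charged"
  if (!(needed %in% residue$classes)) return(FALSE)
  grp <- residue_atom_table()[[normalize_resname(residue$name)]]$charged
  if (is.null(grp)) return(FALSE)
  xyz <- residue_coords(residue, names = grp)
  if (nrow(xyz) == 0L) return(FALSE)
  le(min_distance(feature$coords, xyz), params$contact_dist,
     params$boundary_eps)
}

#' Detect a hydrophobic contact
#'
#' @param feature ligand feature (type "H", or an aromatic ring acting as a
#'   hydrophobe) carrying `coords`.
#' @param residue residue object; must be of the hydrophobic class. Targets
#'   are the residue's side-chain carbon/sulfur atoms.
#' @param params [geometry_params()].
#' @return TRUE/FALSE.
#' @export
detect_hydrophobic <- function(feature, residue, params = geometry_params()) {
  if (!("hydrophobic" %in% residue$classes)) return(FALSE)
  xyz <- residue_coords(residue, region = "sc", elements = c("C", "S"))
  if (nrow(xyz) == 0L) return(FALSE)
  le(min_distance(feature$coords, xyz), params$contact_dist,
     params$boundary_eps)
}

#' Detect a distance-only polar contact
#'
#' @param feature ligand feature of type "A" or "D" carrying `coords`.
#' @param residue residue object; must be of the polar class. Targets are the
#'   residue's polar side-chain heavy atoms.
#' @param params [geometry_params()].
#' @return TRUE/FALSE.
#' @export
detect_polar <- function(feature, residue, params = geometry_params()) {
  if (!("polar" %in% residue$classes)) return(FALSE)
  grp <- residue_atom_table()[[normalize_resname(residue$name)]]$polar
  if (is.null(grp)) return(FALSE)
  xyz <- residue_coords(residue, names = grp)
  if (nrow(xyz) == 0L) return(FALSE)
  le(min_distance(feature$coords, xyz), params$contact_dist,
     params$boundary_eps)
}

ring_geom_of <- function(x) {
  if (!is.null(x$normal) && !is.null(x$centroid)) return(x)
  if (!is.null(x$ring_normal)) return(list(centroid = x$centroid,
                                           normal = x$ring_normal))
  if (!is.null(x$coords)) return(best_fit_plane(x$coords))
  stop("cannot derive ring geometry", call. = FALSE)
}

#' Classify an aromatic-aromatic contact
#'
#' Let d be the centroid-centroid distance and theta the interplanar angle
#' folded to `[0, 90]` degrees. Face-to-face requires `d <= pi_ff_dist` and
#' `theta <= pi_ff_angle_max`; edge-to-face requires `d <= pi_ef_dist` and
#' `theta >= pi_ef_angle_min`. Face-to-face takes precedence when both hold.
#'
#' @param ring_a,ring_b aromatic features (from [assign_features()]), plain
#'   lists with `centroid`/`normal`, or lists with ring `coords`.
#' @param params [geometry_params()].
#' @return one of "face_to_face", "edge_to_face", "none".
#' @export
detect_aromatic <- function(ring_a, ring_b, params = geometry_params()) {
  a <- ring_geom_of(ring_a)
  b <- ring_geom_of(ring_b)
  eps <- params$boundary_eps
  d <- vnorm(a$centroid - b$centroid)
  theta <- folded_angle_deg(a$normal, b$normal)
  if (le(d, params$pi_ff_dist, eps) && le(theta, params$pi_ff_angle_max, eps)) {
    return("face_to_face")
  }
  if (le(d, params$pi_ef_dist, eps) && ge(theta, params$pi_ef_angle_min, eps)) {
    return("edge_to_face")
  }
  "none"
}

#' Detect a pi-cation interaction
#'
#' Distance-only criterion: ring centroid to cation-group centroid within
#' `pi_cation_dist`. Evaluated in both directions by the matrix builder
#' (ligand ring vs residue cation fills the R row; ligand cation vs residue
#' ring fills the P row, both in the aromatic column).
#'
#' @param ring_centroid,cation_centroid 3-vectors.
#' @param params [geometry_params()].
#' @return TRUE/FALSE.
#' @export
detect_pi_cation <- function(ring_centroid, cation_centroid,
                             params = geometry_params()) {
  le(vnorm(as.numeric(ring_centroid) - as.numeric(cation_centroid)),
     params$pi_cation_dist, params$boundary_eps)
}

# ---- residue-side helper geometry -----------------------------------------

residue_rings <- function(residue) {
  tab <- residue_atom_table()[[normalize_resname(residue$name)]]
  if (is.null(tab$rings)) return(list())
  out <- list()
  for (ring in tab$rings) {
    xyz <- residue_coords(residue, names = ring)
    if (nrow(xyz) >= length(ring) - 1L && nrow(xyz) >= 3L) {
      out <- c(out, list(best_fit_plane(xyz)))
    }
  }
  out
}

residue_cation_centroid <- function(residue) {
  if (!("positively_charged" %in% residue$classes)) return(NULL)
  grp <- residue_atom_table()[[normalize_resname(residue$name)]]$charged
  if (is.null(grp)) return(NULL)
  xyz <- residue_coords(residue, names = grp)
  if (nrow(xyz) == 0L) return(NULL)
  colMeans(xyz)
}

# donors: list of (Y, hs, region); acceptors: list of (X, ante, region)
residue_donors <- function(residue) {
  at <- residue$atoms
  tab <- residue_atom_table()[[normalize_resname(residue$name)]]
  hxyz <- coord_matrix(at[at$is_h, , drop = FALSE])
  donor_entry <- function(name, region) {
    i <- which(at$name == name & !at$is_h)
    if (length(i) != 1L) return(NULL)
    y <- c(at$x[i], at$y[i], at$z[i])
    hs <- if (nrow(hxyz)) {
      hxyz[sqrt(colSums((t(hxyz) - y)^2)) <= 1.3, , drop = FALSE]
    } else matrix(numeric(0), 0, 3)
    list(Y = y, hs = hs, region = region)
  }
  entries <- list(donor_entry("N", "bb"))
  for (nm in tab$donors) entries <- c(entries, list(donor_entry(nm, "sc")))
  Filter(Negate(is.null), entries)
}

residue_acceptors <- function(residue) {
  at <- residue$atoms
  tab <- residue_atom_table()[[normalize_resname(residue$name)]]
  heavy <- coord_matrix(at[!at$is_h, , drop = FALSE])
  acceptor_entry <- function(name, region) {
    i <- which(at$name == name & !at$is_h)
    if (length(i) != 1L) return(NULL)
    x <- c(at$x[i], at$y[i], at$z[i])
    d <- sqrt(colSums((t(heavy) - x)^2))
    ante <- heavy[d > 0.4 & d <= 1.8, , drop = FALSE]
    list(X = x, ante = ante, region = region)
  }
  entries <- list(acceptor_entry("O", "bb"), acceptor_entry("OXT", "bb"))
  for (nm in tab$acceptors) entries <- c(entries, list(acceptor_entry(nm, "sc")))
  Filter(Negate(is.null), entries)
}

ligand_antecedents <- function(ligand, atom_idx) {
  b <- ligand$bonds
  partners <- c(b$a2[b$a1 == atom_idx], b$a1[b$a2 == atom_idx])
  partners <- partners[!ligand$atoms$is_h[partners]]
  coord_matrix(ligand$atoms[partners, , drop = FALSE])
}

# ---- block assembly --------------------------------------------------------

empty_block <- function() {
  matrix(0L, nrow = 7L, ncol = 9L,
         dimnames = list(FEATURE_TYPES, INTERACTION_TYPES))
}

#' Build the 7x9 interaction block for one residue
#'
#' Applies every detector between the ligand's pharmacophore features and the
#' residue and increments the block cells, with the redundancy rules: one
#' feature instance increments a cell at most once per residue; a fired
#' hydrogen bond suppresses the polar column for the same feature-residue
#' pair; face-to-face takes precedence over edge-to-face; the vdW row counts
#' each region column at most once per residue. Cells outside the
#' incrementable mask stay zero.
#'
#' @param features a `sift2d_features` list from [assign_features()].
#' @param residue residue object.
#' @param params [geometry_params()].
#' @param mask [increment_mask()].
#' @param ligand the ligand the features refer to; defaults to the ligand the
#'   features were assigned from.
#' @return 7x9 integer matrix with feature rownames / interaction colnames.
#' @export
build_block <- function(features, residue, params = geometry_params(),
                        mask = increment_mask(), ligand = NULL) {
  if (is.null(ligand)) ligand <- attr(features, "ligand")
  if (is.null(ligand)) stop("build_block() needs the ligand", call. = FALSE)
  counts <- empty_block()
  rings <- residue_rings(residue)
  cation <- residue_cation_centroid(residue)
  donors <- residue_donors(residue)
  acceptors <- residue_acceptors(residue)

  for (f in features) {
    f$coords <- coord_matrix(ligand$atoms[f$atom_indices, , drop = FALSE])
    f$ligand <- ligand
    cols <- character(0)
    regions <- character(0)
    if (f$type == "A") {
      for (don in donors) {
        hit <- any(vapply(seq_along(f$atom_indices), function(k) {
          detect_hbond(don$Y, don$hs, f$coords[k, ],
                       ligand_antecedents(ligand, f$atom_indices[k]), params)
        }, logical(1)))
        if (hit) {
          cols <- c(cols, "D")
          regions <- c(regions, don$region)
        }
      }
      if (!("D" %in% cols) && detect_polar(f, residue, params)) {
        cols <- c(cols, "P")
        regions <- c(regions, "sc")
      }
    } else if (f$type == "D") {
      for (k in seq_along(f$atom_indices)) {
        hs <- ligand_donor_hs(ligand, f$atom_indices[k])
        for (acc in acceptors) {
          if (detect_hbond(f$coords[k, ], hs, acc$X, acc$ante, params)) {
            cols <- c(cols, "A")
            regions <- c(regions, acc$region)
          }
        }
      }
      if (!("A" %in% cols) && detect_polar(f, residue, params)) {
        cols <- c(cols, "P")
        regions <- c(regions, "sc")
      }
    } else if (f$type == "H") {
      if (detect_hydrophobic(f, residue, params)) {
        cols <- c(cols, "H")
        regions <- c(regions, "sc")
      }
    } else if (f$type %in% c("N", "P")) {
      if (detect_charged(f, residue, params)) {
        cols <- c(cols, "C")
        regions <- c(regions, "sc")
      }
      if (f$type == "P" && length(rings)) {
        hit <- any(vapply(rings, function(rg) {
          detect_pi_cation(rg$centroid, f$centroid, params)
        }, logical(1)))
        if (hit) {
          cols <- c(cols, "R")
          regions <- c(regions, "sc")
        }
      }
    } else if (f$type == "R") {
      if (length(rings)) {
        stack <- vapply(rings, function(rg) {
          detect_aromatic(f, rg, params)
        }, character(1))
        if (any(stack != "none")) {
          cols <- c(cols, "R")
          regions <- c(regions, "sc")
        }
      }
      if (!is.null(cation) && detect_pi_cation(f$centroid, cation, params)) {
        cols <- c(cols, "R")
        regions <- c(regions, "sc")
      }
      if (detect_hydrophobic(f, residue, params)) {
        cols <- c(cols, "H")
        regions <- c(regions, "sc")
      }
    }
    if (length(cols)) {
      fired <- unique(c("Any", c(bb = "BB", sc = "SC")[regions], cols))
      for (col in fired) {
        if (mask[f$type, col]) {
          counts[f$type, col] <- counts[f$type, col] + 1L
        }
      }
    }
  }

  # vdW row: whole-ligand steric contact, each region column at most once
  lig_heavy <- coord_matrix(ligand$atoms[!ligand$atoms$is_h, , drop = FALSE])
  cf <- detect_contact(lig_heavy, residue, params)
  if (cf$any && mask["vdW", "Any"]) counts["vdW", "Any"] <- 1L
  if (cf$bb && mask["vdW", "BB"]) counts["vdW", "BB"] <- 1L
  if (cf$sc && mask["vdW", "SC"]) counts["vdW", "SC"] <- 1L

  counts * (mask * 1L)
}

#' Build the full 2D-SIFt interaction matrix of a complex
#'
#' Assigns pharmacophore features to the ligand (unless supplied) and
#' concatenates one [build_block()] per residue in residue order.
#'
#' @param complex a `sift2d_complex`.
#' @param params [geometry_params()].
#' @param mask [increment_mask()].
#' @param smarts_defs optional feature-definition file/list for
#'   [assign_features()].
#' @param features optional pre-assigned `sift2d_features`.
#' @return a `sift2d_matrix` (see [interaction_matrix()]).
#' @export
build_matrix <- function(complex, params = geometry_params(),
                         mask = increment_mask(), smarts_defs = NULL,
                         features = NULL) {
  if (is.null(features)) {
    features <- assign_features(complex$ligand, smarts_defs)
  }
  attr(features, "ligand") <- complex$ligand
  blocks <- lapply(complex$residues, function(r) {
    build_block(features, r, params, mask, ligand = complex$ligand)
  })
  residues <- tibble::tibble(
    chain = vapply(complex$residues, `[[`, "", "chain"),
    seqnum = vapply(complex$residues, `[[`, 0L, "seqnum"),
    insertion_code = vapply(complex$residues, `[[`, "", "insertion_code"),
    name = vapply(complex$residues, `[[`, "", "name"),
    generic_number = vapply(complex$residues, `[[`, "", "generic_number"),
    present = TRUE)
  interaction_matrix(blocks, residues, complex_id = complex$identifier,
                     params = params, mask = mask)
}
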
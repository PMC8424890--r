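# Programmatic toy complexes with analytically known descriptors. Residue
# templates use idealized internal coordinates; probes are placed at exact
# requested geometry, so the expected 7x9 block can be derived by direct
# application of the interaction rules to the coordinates, independently of
# the detection engine.

# -- internal-coordinate atom placement (NeRF construction) ------------------
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# z-matrix side-chain definitions; each row: name element ref_a ref_b ref_c
# bond angle dihedral. Backbone N/CA/C/O (+ amide H) is shared.
SIDECHAIN_ZMAT <- list(
  GLY = character(0),
  ALA = c("CB C N C CA 1.53 110 122"),
  VAL = c("CB C N C CA 1.54 110 122",
          "CG1 C N CA CB 1.54 112 180",
          "CG2 C N CA CB 1.54 112 60"),
  LEU = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.53 114 180",
          "CD1 C CA CB CG 1.53 112 180",
          "CD2 C CA CB CG 1.53 112 60"),
  SER = c("CB C N C CA 1.53 110 122",
          "OG O N CA CB 1.42 110 180",
          "HG H CA CB OG 0.97 108 180"),
  ASN = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.52 112 180",
          "OD1 O CA CB CG 1.23 121 180",
          "ND2 N CA CB CG 1.33 117 0",
          "HD21 H CB CG ND2 1.01 120 0",
          "HD22 H CB CG ND2 1.01 120 180"),
  ASP = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.52 112 180",
          "OD1 O CA CB CG 1.25 119 180",
          "OD2 O CA CB CG 1.25 119 0"),
  GLU = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.53 114 180",
          "CD C CA CB CG 1.52 112 180",
          "OE1 O CB CG CD 1.25 119 180",
          "OE2 O CB CG CD 1.25 119 0"),
  LYS = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.53 114 180",
          "CD C CA CB CG 1.53 112 180",
          "CE C CB CG CD 1.53 112 180",
          "NZ N CG CD CE 1.49 112 180",
          "HZ1 H CD CE NZ 1.01 109.5 60",
          "HZ2 H CD CE NZ 1.01 109.5 180",
          "HZ3 H CD CE NZ 1.01 109.5 300"),
  ARG = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.53 114 180",
          "CD C CA CB CG 1.53 112 180",
          "NE N CB CG CD 1.46 112 180",
          "HE H CG CD NE 1.01 118 0",
          "CZ C CG CD NE 1.33 124 180",
          "NH1 N CD NE CZ 1.33 120 0",
          "NH2 N CD NE CZ 1.33 120 180",
          "HH11 H NE CZ NH1 1.01 120 0",
          "HH12 H NE CZ NH1 1.01 120 180",
          "HH21 H NE CZ NH2 1.01 120 0",
          "HH22 H NE CZ NH2 1.01 120 180"),
  PHE = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.50 113 180",
          "CD1 C CA CB CG 1.39 120 90",
          "CD2 C CA CB CG 1.39 120 270",
          "CE1 C CB CG CD1 1.39 120 180",
          "CE2 C CB CG CD2 1.39 120 180",
          "CZ C CG CD1 CE1 1.39 120 0"),
  TYR = c("CB C N C CA 1.53 110 122",
          "CG C N CA CB 1.50 113 180",
          "CD1 C CA CB CG 1.39 120 90",
          "CD2 C CA CB CG 1.39 120 270",
          "CE1 C CB CG CD1 1.39 120 180",
          "CE2 C CB CG CD2 1.39 120 180",
          "CZ C CG CD1 CE1 1.39 120 0",
          "OH O CD1 CE1 CZ 1.36 120 180",
          "HH H CE1 CZ OH 0.97 109 180"))

#' Idealized one-residue template
#'
#' Builds a residue with standard atom naming from idealized internal
#' coordinates (shared N/CA/C/O backbone with amide hydrogen; side chain per
#' template). Geometry is exact by construction, which makes expected
#' interaction outcomes analytically derivable.
#'
#' @param name one of GLY, ALA, VAL, LEU, SER, ASN, ASP, GLU, LYS, ARG, PHE,
#'   TYR.
#' @param chain,seqnum identity of the emitted residue.
#' @param oxt add a C-terminal OXT atom.
#' @return a residue object as produced by [parse_complex()].
#' @export
residue_template <- function(name, chain = "A", seqnum = 1L, oxt = FALSE) {
  if (!name %in% names(SIDECHAIN_ZMAT)) {
    stop("unsupported residue template: ", name, call. = FALSE)
  }
  pos <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0))
  pos$C <- pos$CA + 1.52 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.23, 121, 135)
  pos$H <- place_atom(pos$C, pos$CA, pos$N, 1.01, 119, 180)
  elements <- c(N = "N", CA = "C", C = "C", O = "O", H = "H")
  if (oxt) {
    pos$OXT <- place_atom(pos$N, pos$CA, pos$C, 1.25, 117, -45)
    elements["OXT"] <- "O"
  }
  for (row in SIDECHAIN_ZMAT[[name]]) {
    f <- strsplit(row, " +")[[1]]
    pos[[f[1]]] <- place_atom(pos[[f[3]]], pos[[f[4]]], pos[[f[5]]],
                              as.numeric(f[6]), as.numeric(f[7]),
                              as.numeric(f[8]))
    elements[f[1]] <- f[2]
  }
  xyz <- do.call(rbind, pos)
  new_residue(chain, seqnum, "", name,
              atoms_tibble(names(pos), unname(elements[names(pos)]),
                           xyz[, 1], xyz[, 2], xyz[, 3]))
}

# -- probe molecules (local frame: contact atom at origin, tail along +z) ----

tetra_dirs <- function() {
  a <- 109.47 * pi / 180
  rbind(c(0, 0, 1),
        c(sin(a) * cos(0), sin(a) * sin(0), cos(a)),
        c(sin(a) * cos(2 * pi / 3), sin(a) * sin(2 * pi / 3), cos(a)),
        c(sin(a) * cos(4 * pi / 3), sin(a) * sin(4 * pi / 3), cos(a)))
}

PROBE_NAMES <- c("aromatic_ring", "ammonium", "carboxylate", "hydroxyl_donor",
                 "carbonyl_acceptor", "methyl")

probe_geometry <- function(probe) {
  deg <- pi / 180
  switch(probe,
    methyl = {
      h <- 1.09 * tetra_dirs()
      list(el = c("C", rep("H", 4)),
           xyz = rbind(c(0, 0, 0), h),
           bonds = cbind(1L, 2:5), charges = integer(5),
           contact = 1L,
           features = list(list(type = "H", atoms = 1L)))
    },
    aromatic_ring = {
      ang <- seq(0, 300, by = 60) * deg
      cc <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
      hh <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
      list(el = c(rep("C", 6), rep("H", 6)),
           xyz = rbind(cc, hh),
           bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(1:6, 7:12)),
           orders = c(c(2, 1, 2, 1, 2, 1), rep(1, 6)),
           charges = integer(12), contact = 0L,  # contact = ring centroid
           features = list(list(type = "R", atoms = 1:6)))
    },
    ammonium = {
      hn <- 0.94 * -tetra_dirs()[2:4, ]  # point into the -z hemisphere
      hc <- sweep(1.09 * tetra_dirs()[2:4, ], 2, c(0, 0, 1.49), "+")
      list(el = c("N", "C", rep("H", 6)),
           xyz = rbind(c(0, 0, 0), c(0, 0, 1.49), hn, hc),
           bonds = rbind(c(1, 2), cbind(1L, 3:5), cbind(2L, 6:8)),
           charges = c(1L, integer(7)), contact = 1L,
           features = list(list(type = "D", atoms = 1L),
                           list(type = "P", atoms = 1L)))
    },
    carboxylate = {
      o1 <- c(0, 0, 0)
      cc <- c(0, 0, 1.25)
      o2 <- cc + 1.25 * c(sin(126 * deg), 0, -cos(126 * deg))
      cm <- cc + 1.51 * c(-sin(117 * deg), 0, -cos(117 * deg))
      hm <- sweep(1.09 * rbind(c(-0.94, 0, 0.33), c(0.47, 0.82, 0.33),
                               c(0.47, -0.82, 0.33)), 2, cm, "+")
      list(el = c("O", "C", "O", "C", rep("H", 3)),
           xyz = rbind(o1, cc, o2, cm, hm),
           bonds = rbind(c(1, 2), c(2, 3), c(2, 4), cbind(4L, 5:7)),
           orders = c(1, 2, 1, 1, 1, 1),
           charges = c(-1L, integer(6)), contact = 1L,
           features = list(list(type = "A", atoms = 1L),
                           list(type = "A", atoms = 3L),
                           list(type = "N", atoms = c(1L, 3L)),
                           list(type = "H", atoms = 4L)))
    },
    hydroxyl_donor = {
      ho <- c(0, 0, 0)
      o <- c(0, 0, 0.97)
      cc <- o + 1.43 * c(sin(71 * deg), 0, cos(71 * deg))
      hc <- sweep(1.09 * rbind(c(0.2, 0.93, 0.3), c(0.2, -0.93, 0.3),
                               c(0.95, 0, -0.3)), 2, cc, "+")
      list(el = c("H", "O", "C", rep("H", 3)),
           xyz = rbind(ho, o, cc, hc),
           bonds = rbind(c(1, 2), c(2, 3), cbind(3L, 4:6)),
           charges = integer(6), contact = 1L,
           features = list(list(type = "A", atoms = 2L),
                           list(type = "D", atoms = 2L)))
    },
    carbonyl_acceptor = {
      o <- c(0, 0, 0)
      c2 <- c(0, 0, 1.22)
      c1 <- c2 + 1.51 * c(sin(59 * deg), 0, cos(59 * deg))
      c3 <- c2 + 1.51 * c(-sin(59 * deg), 0, cos(59 * deg))
      list(el = c("O", "C", "C", "C"),
           xyz = rbind(o, c2, c1, c3),
           bonds = rbind(c(1, 2), c(2, 3), c(2, 4)),
           orders = c(2, 1, 1),
           charges = integer(4), contact = 1L,
           features = list(list(type = "A", atoms = 1L),
                           list(type = "H", atoms = 3L),
                           list(type = "H", atoms = 4L)))
    },
    stop("unsupported probe: ", probe, call. = FALSE))
}

# V2000 MOL block from probe geometry
mol_block <- function(geom, title = "probe") {
  n <- nrow(geom$xyz)
  nb <- nrow(geom$bonds)
  orders <- if (is.null(geom$orders)) rep(1L, nb) else geom$orders
  lines <- c(title, "  sift2d", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3], geom$el),
             sprintf("%3d%3d%3d  0  0  0  0", geom$bonds[, 1], geom$bonds[, 2],
                     orders))
  chg <- which(geom$charges != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, geom$charges[chg]),
                                    collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

# PDB ATOM records for a list of residues
residues_pdb <- function(residues) {
  serial <- 0L
  lines <- unlist(lapply(residues, function(r) {
    at <- r$atoms
    s <- serial + seq_len(nrow(at))
    serial <<- max(s)
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            s, ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
            r$name, r$chain, r$seqnum, at$x, at$y, at$z,
            toupper(at$element))
  }))
  c(lines, "TER", "END")
}

# contact anchor atom and outward direction for each (probe, template) pair
anchor_info <- function(probe, res) {
  nm <- res$name
  at <- res$atoms
  atom_xyz <- function(name) {
    i <- which(at$name == name)
    c(at$x[i], at$y[i], at$z[i])
  }
  generic_anchor <- c(GLY = "CA", ALA = "CB", VAL = "CG1", LEU = "CD1",
                      SER = "OG", ASN = "OD1", ASP = "OD1", GLU = "OE1",
                      LYS = "NZ", ARG = "NH1", PHE = "CZ", TYR = "CZ")
  ca <- atom_xyz("CA")
  if (probe == "hydroxyl_donor") {
    # anchor on the residue acceptor, approach along its lone-pair axis
    acc <- switch(nm, SER = c("OG", "CB"), ASN = c("OD1", "CG"),
                  ASP = c("OD1", "CG"), GLU = c("OE1", "CD"),
                  GLY = c("O", "C"), ALA = c("O", "C"),
                  stop("unsupported acceptor template for hydroxyl_donor: ",
                       nm, call. = FALSE))
    x <- atom_xyz(acc[1])
    return(list(point = x, dir = unit(x - atom_xyz(acc[2]))))
  }
  if (probe == "carbonyl_acceptor") {
    don <- switch(nm, SER = c("HG", "OG"), ASN = c("HD21", "ND2"),
                  LYS = c("HZ1", "NZ"), ARG = c("HH11", "NH1"),
                  GLY = c("H", "N"), ALA = c("H", "N"),
                  stop("unsupported donor template for carbonyl_acceptor: ",
                       nm, call. = FALSE))
    h <- atom_xyz(don[1])
    return(list(point = h, dir = unit(h - atom_xyz(don[2]))))
  }
  if (probe %in% c("aromatic_ring", "ammonium") && nm %in% c("PHE", "TYR")) {
    ring <- residue_rings(res)[[1L]]
    dir <- ring$normal
    if (sum(dir * (ring$centroid - ca)) < 0) dir <- -dir
    return(list(point = ring$centroid, dir = dir))
  }
  a <- atom_xyz(generic_anchor[[nm]])
  list(point = a, dir = unit(a - ca))
}

#' Fixture specification
#'
#' @param probe one of aromatic_ring, ammonium, carboxylate, hydroxyl_donor,
#'   carbonyl_acceptor, methyl.
#' @param residue_template a template name for [residue_template()].
#' @param distance placement distance in Angstrom: probe contact atom (or
#'   ring centroid) to the residue anchor (H...acceptor distance for donor
#'   probes, centroid-centroid for rings).
#' @param angle ring interplanar angle in degrees (aromatic probe only).
#' @param seed integer seed recorded in the spec.
#' @return a `sift2d_fixture_spec` list.
#' @export
fixture_spec <- function(probe, residue_template, distance, angle = 0,
                         seed = 1L) {
  probe <- match.arg(probe, PROBE_NAMES)
  structure(list(probe = probe, residue_template = residue_template,
                 distance = distance, angle = angle, seed = as.integer(seed)),
            class = "sift2d_fixture_spec")
}

rotation_from_z <- function(u) {
  u <- unit(u)
  if (sum(u * c(0, 0, 1)) > 1 - 1e-12) return(diag(3))
  if (sum(u * c(0, 0, 1)) < -1 + 1e-12) return(rotation_matrix(c(1, 0, 0), 180))
  axis <- pracma_cross(c(0, 0, 1), u)
  rotation_matrix(axis, acos(sum(u * c(0, 0, 1))) * 180 / pi)
}

#' Build a one-residue pair fixture with its analytically expected block
#'
#' Places the probe at the exact requested geometry against an idealized
#' residue template, emits the complex through the real PDB/MOL parsers, and
#' derives the expected 7x9 block by direct application of the interaction
#' rules to the coordinates (a code path independent of the detection
#' engine).
#'
#' @param spec a [fixture_spec()].
#' @param params [geometry_params()] under which the expected block is
#'   derived.
#' @return list with `complex`, `expected` (7x9 integer block), `pdb_text`,
#'   `mol_text`, `spec`.
#' @export
make_pair_fixture <- function(spec, params = geometry_params()) {
  res <- residue_template(spec$residue_template)
  geom <- probe_geometry(spec$probe)
  anchor <- anchor_info(spec$probe, res)
  R <- rotation_from_z(anchor$dir)
  xyz <- geom$xyz
  if (spec$probe == "aromatic_ring" && spec$angle != 0) {
    xyz <- xyz %*% t(rotation_matrix(c(1, 0, 0), spec$angle))
  }
  xyz <- xyz %*% t(R)
  target <- anchor$point + spec$distance * anchor$dir
  origin <- if (geom$contact == 0L) colMeans(xyz[1:6, , drop = FALSE])
            else xyz[geom$contact, ]
  xyz <- sweep(xyz, 2, target - origin, "+")
  geom$xyz <- xyz

  res_xyz <- coord_matrix(res$atoms)
  clash <- min_distance(xyz[geom$el != "H", , drop = FALSE], res_xyz)
  if (clash < 1.0) {
    stop("unrealizable fixture placement: probe clashes with the residue (",
         sprintf("%.2f", clash), " Angstrom)", call. = FALSE)
  }

  mol_text <- mol_block(geom, paste0(spec$probe, "_", spec$residue_template))
  pdb_text <- residues_pdb(list(res))
  cx <- parse_complex(pdb_text, mol_text,
                      identifier = sprintf("%s_%s_d%.2f_a%.1f", spec$probe,
                                           spec$residue_template,
                                           spec$distance, spec$angle))
  expected <- analytic_block(geom, res, params)
  list(complex = cx, expected = expected, pdb_text = pdb_text,
       mol_text = mol_text, spec = spec)
}

# ---- analytic expected block (independent of the engine) -------------------

AN_HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                    "CYS")
AN_POLAR <- c("SER", "THR", "ASN", "GLN", "TYR", "HIS", "CYS", "TRP")
AN_NEG <- c("ASP", "GLU")
AN_POS <- c("LYS", "ARG", "HIS")
AN_AROM <- c("PHE", "TYR", "TRP", "HIS")
AN_POLAR_ATOMS <- list(SER = "OG", THR = "OG1", ASN = c("OD1", "ND2"),
                       GLN = c("OE1", "NE2"), TYR = "OH",
                       HIS = c("ND1", "NE2"), CYS = "SG", TRP = "NE1")
AN_CHARGED_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                         LYS = "NZ", ARG = c("CZ", "NE", "NH1", "NH2"),
                         HIS = c("ND1", "NE2"))
AN_DONORS <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                  GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG")
AN_ACCEPTORS <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                     GLN = "OE1", ASP = c("OD1", "OD2"),
                     GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))
AN_RINGS <- list(PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                 TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                 HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
                 TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                            c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

an_mindist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

an_plane <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

an_hbond <- function(Y, hs, X, ante, p) {
  if (nrow(hs) == 0L) return(sqrt(sum((Y - X)^2)) <= p$contact_dist + 1e-6)
  for (i in seq_len(nrow(hs))) {
    H <- hs[i, ]
    d <- if (p$hbond_dist_mode == "hx") sqrt(sum((H - X)^2))
         else sqrt(sum((Y - X)^2))
    if (d > p$hbond_dist + 1e-6) next
    v1 <- Y - H; v2 <- X - H
    dev_d <- 180 - acos(max(-1, min(1, sum(v1 * v2) /
                                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (dev_d > p$hbond_donor_angle_max + 1e-6) next
    if (nrow(ante) > 0L) {
      dirs <- sweep(ante, 2, X)
      md <- colMeans(dirs / sqrt(rowSums(dirs^2)))
      if (sqrt(sum(md^2)) > 1e-9) {
        v3 <- H - X
        dev_a <- 180 - acos(max(-1, min(1, sum(md * v3) /
                                          sqrt(sum(md^2) * sum(v3^2))))) *
          180 / pi
        if (dev_a > p$hbond_acceptor_angle_max + 1e-6) next
      }
    }
    return(TRUE)
  }
  FALSE
}

# straight-line application of every interaction rule to the coordinates
analytic_block <- function(geom, res, params) {
  p <- params
  nm <- res$name
  at <- res$atoms
  sel <- function(names) coord_matrix(at[at$name %in% names & !at$is_h, ,
                                         drop = FALSE])
  lig_heavy <- geom$xyz[geom$el != "H", , drop = FALSE]
  lig_h <- geom$xyz[geom$el == "H", , drop = FALSE]
  bb_heavy <- coord_matrix(at[at$region == "bb" & !at$is_h, , drop = FALSE])
  sc_heavy <- coord_matrix(at[at$region == "sc" & !at$is_h, , drop = FALSE])
  counts <- matrix(0L, 7, 9, dimnames = list(FEATURE_TYPES, INTERACTION_TYPES))

  # residue donors/acceptors with geometry
  hxyz <- coord_matrix(at[at$is_h, , drop = FALSE])
  res_heavy <- coord_matrix(at[!at$is_h, , drop = FALSE])
  donors <- list()
  for (dn in c("N", AN_DONORS[[nm]])) {
    i <- which(at$name == dn & !at$is_h)
    if (length(i) != 1L) next
    y <- c(at$x[i], at$y[i], at$z[i])
    hs <- hxyz[sqrt(colSums((t(hxyz) - y)^2)) <= 1.3, , drop = FALSE]
    donors <- c(donors, list(list(Y = y, hs = hs,
                                  region = if (dn == "N") "BB" else "SC")))
  }
  acceptors <- list()
  for (an in c("O", "OXT", AN_ACCEPTORS[[nm]])) {
    i <- which(at$name == an & !at$is_h)
    if (length(i) != 1L) next
    x <- c(at$x[i], at$y[i], at$z[i])
    d <- sqrt(colSums((t(res_heavy) - x)^2))
    acceptors <- c(acceptors, list(list(
      X = x, ante = res_heavy[d > 0.4 & d <= 1.8, , drop = FALSE],
      region = if (an %in% c("O", "OXT")) "BB" else "SC")))
  }
  rings <- lapply(AN_RINGS[[nm]], function(rn) an_plane(sel(rn)))

  bump <- function(row, cols) {
    for (cc in unique(c("Any", cols))) {
      if (increment_mask()[row, cc]) counts[row, cc] <<- counts[row, cc] + 1L
    }
  }

  for (f in geom$features) {
    fc <- geom$xyz[f$atoms, , drop = FALSE]
    cols <- character(0)
    if (f$type == "H") {
      tgt_idx <- at$region == "sc" & !at$is_h & at$element %in% c("C", "S")
      if (nm %in% AN_HYDROPHOBIC && any(tgt_idx) &&
          an_mindist(fc, coord_matrix(at[tgt_idx, , drop = FALSE])) <=
          p$contact_dist + 1e-6) {
        cols <- c("H", "SC")
      }
    } else if (f$type == "A") {
      for (don in donors) {
        hit <- FALSE
        for (k in seq_len(nrow(fc))) {
          aidx <- f$atoms[k]
          nbr <- unique(c(geom$bonds[geom$bonds[, 1] == aidx, 2],
                          geom$bonds[geom$bonds[, 2] == aidx, 1]))
          nbr <- nbr[geom$el[nbr] != "H"]
          if (an_hbond(don$Y, don$hs, fc[k, ],
                       geom$xyz[nbr, , drop = FALSE], p)) hit <- TRUE
        }
        if (hit) cols <- c(cols, "D", don$region)
      }
      if (!("D" %in% cols) && nm %in% AN_POLAR) {
        tgt <- sel(AN_POLAR_ATOMS[[nm]])
        if (nrow(tgt) && an_mindist(fc, tgt) <= p$contact_dist + 1e-6) {
          cols <- c("P", "SC")
        }
      }
    } else if (f$type == "D") {
      for (k in seq_len(nrow(fc))) {
        aidx <- f$atoms[k]
        nbr <- unique(c(geom$bonds[geom$bonds[, 1] == aidx, 2],
                        geom$bonds[geom$bonds[, 2] == aidx, 1]))
        hs <- geom$xyz[nbr[geom$el[nbr] == "H"], , drop = FALSE]
        for (acc in acceptors) {
          if (an_hbond(fc[k, ], hs, acc$X, acc$ante, p)) {
            cols <- c(cols, "A", acc$region)
          }
        }
      }
      if (!("A" %in% cols) && nm %in% AN_POLAR) {
        tgt <- sel(AN_POLAR_ATOMS[[nm]])
        if (nrow(tgt) && an_mindist(fc, tgt) <= p$contact_dist + 1e-6) {
          cols <- c("P", "SC")
        }
      }
    } else if (f$type == "N") {
      if (nm %in% AN_POS &&
          an_mindist(fc, sel(AN_CHARGED_ATOMS[[nm]])) <= p$contact_dist + 1e-6) {
        cols <- c("C", "SC")
      }
    } else if (f$type == "P") {
      if (nm %in% AN_NEG &&
          an_mindist(fc, sel(AN_CHARGED_ATOMS[[nm]])) <= p$contact_dist + 1e-6) {
        cols <- c(cols, "C", "SC")
      }
      ctr <- colMeans(fc)
      for (rg in rings) {
        if (sqrt(sum((rg$centroid - ctr)^2)) <= p$pi_cation_dist + 1e-6) {
          cols <- c(cols, "R", "SC")
        }
      }
    } else if (f$type == "R") {
      pl <- an_plane(fc)
      for (rg in rings) {
        d <- sqrt(sum((pl$centroid - rg$centroid)^2))
        th <- acos(min(1, abs(sum(pl$normal * rg$normal)))) * 180 / pi
        ff <- d <= p$pi_ff_dist + 1e-6 && th <= p$pi_ff_angle_max + 1e-6
        ef <- d <= p$pi_ef_dist + 1e-6 && th >= p$pi_ef_angle_min - 1e-6
        if (ff || ef) cols <- c(cols, "R", "SC")
      }
      if (nm %in% AN_POS) {
        cat_ctr <- colMeans(sel(AN_CHARGED_ATOMS[[nm]]))
        if (sqrt(sum((pl$centroid - cat_ctr)^2)) <= p$pi_cation_dist + 1e-6) {
          cols <- c(cols, "R", "SC")
        }
      }
      tgt_idx <- at$region == "sc" & !at$is_h & at$element %in% c("C", "S")
      if (nm %in% AN_HYDROPHOBIC && any(tgt_idx) &&
          an_mindist(fc, coord_matrix(at[tgt_idx, , drop = FALSE])) <=
          p$contact_dist + 1e-6) {
        cols <- c(cols, "H", "SC")
      }
    }
    if (length(cols)) bump(f$type, unique(cols))
  }

  if (nrow(bb_heavy) && an_mindist(lig_heavy, bb_heavy) <= p$contact_dist + 1e-6) {
    counts["vdW", "BB"] <- 1L
  }
  if (nrow(sc_heavy) && an_mindist(lig_heavy, sc_heavy) <= p$contact_dist + 1e-6) {
    counts["vdW", "SC"] <- 1L
  }
  if (counts["vdW", "BB"] + counts["vdW", "SC"] > 0L) counts["vdW", "Any"] <- 1L
  counts
}

# ---- collections with known averages --------------------------------------

#' Generate a matrix collection with an exactly known cellwise mean
#'
#' Recycles the base fixture specifications to `n` fixtures, applies a small
#' rigid random translation (`perturb`) to each probe, verifies that the
#' analytic expected block is invariant when every distance cutoff is shifted
#' by +/- 0.1 Angstrom and every angle cutoff by +/- 1 degree (the guard
#' margin: jitter provably cannot flip any detector), and computes the
#' interaction matrices through the full pipeline. The known mean of the
#' collection is the average of the analytic expected blocks.
#'
#' @param n collection size.
#' @param base list of [fixture_spec()]s, recycled to length `n`.
#' @param perturb maximum absolute coordinate jitter in Angstrom.
#' @param seed RNG seed; collections are reproducible.
#' @return list of `sift2d_matrix` with attributes `expected_mean` (7x9 real
#'   matrix) and `expected_blocks`.
#' @export
make_collection <- function(n, base, perturb = 0.02, seed = 1L) {
  if (inherits(base, "sift2d_fixture_spec")) base <- list(base)
  specs <- rep(base, length.out = n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- geometry_params()
  mats <- vector("list", n)
  exp_blocks <- vector("list", n)
  for (i in seq_len(n)) {
    fix <- make_pair_fixture(specs[[i]], params)
    geom <- probe_geometry(specs[[i]]$probe)
    # re-derive the placed geometry, then jitter rigidly
    placed <- fix$complex$ligand$atoms
    shift <- stats::runif(3, -perturb, perturb)
    geom$xyz <- coord_matrix(placed) + matrix(shift, nrow(placed), 3,
                                              byrow = TRUE)
    geom$el <- placed$element
    res <- fix$complex$residues[[1L]]
    guard_ok <- check_guard_margin(geom, res, params)
    if (!guard_ok) {
      stop("fixture jitter violates the 0.1 Angstrom boundary guard for spec ",
           i, call. = FALSE)
    }
    exp_blocks[[i]] <- analytic_block(geom, res, params)
    mol_text <- mol_block(geom, "jittered")
    cx <- parse_complex(fix$pdb_text, mol_text,
                        identifier = sprintf("%s#%02d",
                                             fix$complex$identifier, i))
    mats[[i]] <- build_matrix(cx, params)
  }
  attr(mats, "expected_blocks") <- exp_blocks
  attr(mats, "expected_mean") <- Reduce(`+`, exp_blocks) / n
  mats
}

check_guard_margin <- function(geom, res, params) {
  shift_params <- function(delta_d, delta_a) {
    p <- unclass(params)
    for (k in c("contact_dist", "hbond_dist", "pi_ff_dist", "pi_ef_dist",
                "pi_cation_dist")) p[[k]] <- p[[k]] + delta_d
    for (k in c("hbond_donor_angle_max", "pi_ff_angle_max")) {
      p[[k]] <- p[[k]] + delta_a
    }
    p$hbond_acceptor_angle_max <- min(180, p$hbond_acceptor_angle_max + delta_a)
    p$pi_ef_angle_min <- p$pi_ef_angle_min - delta_a
    do.call(geometry_params, p)
  }
  identical(analytic_block(geom, res, shift_params(-0.1, -1)),
            analytic_block(geom, res, shift_params(0.1, 1)))
}

#' Generate a random small complex for property testing
#'
#' Scatters 1-5 idealized residues at random orientations and distances
#' around a randomly chosen probe ligand, rejecting placements that clash.
#' Emits the complex through the real parsers.
#'
#' @param n_residues number of residues (1-5).
#' @param probe probe name, or NULL to sample one.
#' @param seed RNG seed.
#' @return a `sift2d_complex`.
#' @export
make_random_complex <- function(n_residues = 3L, probe = NULL, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(probe)) probe <- sample(PROBE_NAMES, 1L)
  geom <- probe_geometry(probe)
  templates <- c("GLY", "ALA", "VAL", "LEU", "SER", "ASN", "ASP", "GLU",
                 "LYS", "ARG", "PHE", "TYR")
  lig_heavy <- geom$xyz[geom$el != "H", , drop = FALSE]
  residues <- list()
  placed_xyz <- lig_heavy
  for (i in seq_len(n_residues)) {
    for (attempt in 1:50) {
      r <- residue_template(sample(templates, 1L), seqnum = i)
      ax <- unit(stats::rnorm(3))
      R <- rotation_matrix(unit(stats::rnorm(3)), stats::runif(1, 0, 360))
      d <- stats::runif(1, 2.5, 7.5)
      xyz <- coord_matrix(r$atoms) %*% t(R)
      ctr <- colMeans(xyz)
      xyz <- sweep(xyz, 2, d * ax + colMeans(lig_heavy) - ctr, "+")
      if (min_distance(xyz, placed_xyz) >= 1.5) {
        r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
        residues <- c(residues, list(r))
        placed_xyz <- rbind(placed_xyz, xyz)
        break
      }
    }
  }
  pdb_text <- residues_pdb(residues)
  parse_complex(pdb_text, mol_block(geom, probe),
                identifier = sprintf("random_%s_seed%d", probe, seed))
}

#' Write a fixture to PDB + MOL files
#'
#' @param fixture result of [make_pair_fixture()].
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(fixture, dir, stem = fixture$complex$identifier) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(stem, ".pdb"))
  mol <- file.path(dir, paste0(stem, ".mol"))
  writeLines(fixture$pdb_text, pdb)
  writeLines(fixture$mol_text, mol)
  c(pdb = pdb, mol = mol)
}
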
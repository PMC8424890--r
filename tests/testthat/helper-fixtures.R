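# shared helpers: tiny hand-written structures and geometry utilities

# 2-residue PDB (ALA-GLY) with amide hydrogens, plus a water that parsers
# must drop; coordinates are idealized template geometry shifted per residue
two_residue_pdb <- function(with_water = FALSE, het = NULL) {
  ala <- sift2d::residue_template("ALA", seqnum = 1L)
  gly <- sift2d::residue_template("GLY", seqnum = 2L)
  gly$atoms$x <- gly$atoms$x + 4.0
  lines <- sift2d:::residues_pdb(list(ala, gly))
  body <- lines[lines != "END" & lines != "TER"]
  if (with_water) {
    body <- c(body,
              "HETATM  900  O   HOH A 501      10.000  10.000  10.000  1.00  0.00           O")
  }
  if (!is.null(het)) body <- c(body, het)
  c(body, "TER", "END")
}

methanol_mol <- function(shift = c(0, 0, 0)) {
  g <- sift2d:::probe_geometry("hydroxyl_donor")
  g$xyz <- sweep(g$xyz, 2, shift, "+")
  sift2d:::mol_block(g, "methanol")
}

# rigid-body transform of a parsed complex (rotation + translation)
transform_complex <- function(cx, R, t) {
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + t[1]
    df$y <- xyz[, 2] + t[2]
    df$z <- xyz[, 3] + t[3]
    df
  }
  cx$residues <- lapply(cx$residues, function(r) {
    r$atoms <- move(r$atoms)
    r
  })
  cx$ligand$atoms <- move(cx$ligand$atoms)
  cx
}

random_rotation <- function() {
  sift2d:::rotation_matrix(sift2d:::unit(stats::rnorm(3)),
                           stats::runif(1, 0, 360))
}

# independent straight-line oracle for a whole complex built around a known
# probe: applies sift2d's analytic rule re-implementation residue by residue
oracle_matrix_blocks <- function(cx, probe, params = geometry_params()) {
  geom <- sift2d:::probe_geometry(probe)
  geom$xyz <- sift2d:::coord_matrix(cx$ligand$atoms)
  geom$el <- cx$ligand$atoms$element
  lapply(cx$residues, function(r) sift2d:::analytic_block(geom, r, params))
}

# relabel a 1-residue matrix with a generic number
attach_generic_numbers_matrix <- function(m, gn) {
  m$residues$generic_number <- gn
  m
}

expect_block_cells <- function(block, cells, value = 1L) {
  for (cell in cells) {
    expect_equal(block[cell[1], cell[2]], value,
                 info = paste("cell", cell[1], cell[2]))
  }
}
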
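test_that("min_distance is the minimum pairwise Euclidean distance", {
  expect_equal(min_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5.0)
  expect_equal(min_distance(rbind(c(1, 2, 3)), rbind(c(1, 2, 3))), 0.0)
  expect_equal(min_distance(rbind(c(0, 0, 0), c(10, 0, 0)),
                            rbind(c(0, 0, 2))), 2.0)
  expect_error(min_distance(matrix(numeric(0), 0, 3), rbind(c(0, 0, 0))),
               "non-empty")
})

test_that("steric contact fires inclusively at 3.5 Angstrom", {
  res <- residue_template("LEU")
  anchor <- sift2d:::anchor_info("methyl", res)
  at <- function(d) matrix(anchor$point + d * anchor$dir, 1)
  expect_true(detect_contact(at(3.5), res)$any)
  expect_true(detect_contact(at(3.5), res)$sc)
  expect_false(detect_contact(at(3.51), res)$any)
  # a probe close to the backbone only
  o <- sift2d:::residue_coords(res, names = "O")[1, ]
  away <- sift2d:::unit(o - sift2d:::residue_coords(res, names = "C")[1, ])
  f <- detect_contact(matrix(o + 2.0 * away, 1), res)
  expect_true(f$any && f$bb)
})

test_that("hydrogen bonds respect the 2.8 Angstrom / 120 / 90 degree rules", {
  Y <- c(0, 0, 0); H <- c(0, 0, 1)
  ante_lin <- function(X) rbind(X + c(0, 0, 1.2))
  X28 <- c(0, 0, 3.8)  # H...X = 2.8, collinear
  expect_true(detect_hbond(Y, rbind(H), X28, ante_lin(X28)))
  X29 <- c(0, 0, 3.9)
  expect_false(detect_hbond(Y, rbind(H), X29, ante_lin(X29)))
  # donor deviation 121 degrees at 2.0 Angstrom fails
  X <- c(0, 0, 3)
  th <- (180 - 121) * pi / 180
  Ybent <- H + c(sin(th), 0, cos(th))
  expect_true(detect_hbond(H + c(sin((180 - 119) * pi / 180), 0,
                                 cos((180 - 119) * pi / 180)),
                           rbind(H), X, ante_lin(X)))
  expect_false(detect_hbond(Ybent, rbind(H), X, ante_lin(X)))
  # acceptor deviation 91 degrees fails, 89 passes
  bent_ante <- function(dev) {
    a <- (180 - dev) * pi / 180
    rbind(X + 1.2 * c(sin(a), 0, -cos(a)))
  }
  expect_true(detect_hbond(Y, rbind(H), X, bent_ante(89)))
  expect_false(detect_hbond(Y, rbind(H), X, bent_ante(91)))
  # degraded mode without hydrogens: heavy-atom distance at contact_dist
  expect_true(detect_hbond(c(0, 0, 0), NULL, c(0, 0, 3.5)))
  expect_false(detect_hbond(c(0, 0, 0), NULL, c(0, 0, 3.6)))
  # heavy-atom distance mode measures Y...X
  p_heavy <- geometry_params(hbond_dist_mode = "heavy", hbond_dist = 3.5)
  X34 <- c(0, 0, 3.4)
  expect_true(detect_hbond(Y, rbind(H), X34, ante_lin(X34), p_heavy))
})

test_that("charged contacts require complementarity within 3.5 Angstrom", {
  make_charged_feature <- function(probe, res, d) {
    anchor <- sift2d:::anchor_info(probe, res)
    type <- if (probe == "carboxylate") "N" else "P"
    list(type = type, coords = matrix(anchor$point + d * anchor$dir, 1))
  }
  arg <- residue_template("ARG")
  expect_true(detect_charged(make_charged_feature("carboxylate", arg, 3.4),
                             arg))
  expect_false(detect_charged(make_charged_feature("carboxylate", arg, 3.6),
                              arg))
  # like charges never fire regardless of distance
  asp <- residue_template("ASP")
  f_neg <- make_charged_feature("carboxylate", asp, 3.0)
  expect_false(detect_charged(f_neg, asp))
  glu <- residue_template("GLU")
  expect_true(detect_charged(make_charged_feature("ammonium", glu, 3.4), glu))
  expect_false(detect_charged(make_charged_feature("ammonium", glu, 3.6), glu))
})

test_that("hydrophobic contacts target side-chain carbons of apolar residues", {
  leu <- residue_template("LEU")
  cd1 <- sift2d:::residue_coords(leu, names = "CD1")[1, ]
  dirv <- sift2d:::unit(cd1 - sift2d:::residue_coords(leu, names = "CA")[1, ])
  f <- function(d) list(type = "H", coords = matrix(cd1 + d * dirv, 1))
  expect_true(detect_hydrophobic(f(3.3), leu))
  expect_false(detect_hydrophobic(f(5.0), leu))
  ser <- residue_template("SER")
  og <- sift2d:::residue_coords(ser, names = "OG")[1, ]
  dv <- sift2d:::unit(og - sift2d:::residue_coords(ser, names = "CA")[1, ])
  expect_false(detect_hydrophobic(list(type = "H",
                                       coords = matrix(og + 3.3 * dv, 1)),
                                  ser))
})

test_that("polar contacts are distance-only against polar side chains", {
  asn <- residue_template("ASN")
  od1 <- sift2d:::residue_coords(asn, names = "OD1")[1, ]
  dv <- sift2d:::unit(od1 - sift2d:::residue_coords(asn, names = "CG")[1, ])
  f <- function(d) list(type = "A", coords = matrix(od1 + d * dv, 1))
  expect_true(detect_polar(f(3.2), asn))
  expect_false(detect_polar(f(3.6), asn))
  val <- residue_template("VAL")
  expect_false(detect_polar(list(type = "A",
                                 coords = sift2d:::residue_coords(
                                   val, names = "CG1") + 0), val))
})

test_that("ring stacking classification follows distance and angle jointly", {
  ring_at <- function(d, angle) {
    nb <- c(sin(angle * pi / 180), 0, cos(angle * pi / 180))
    list(coords = sift2d:::ring_coords(c(0, 0, d), nb))
  }
  base <- list(coords = sift2d:::ring_coords(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(detect_aromatic(base, ring_at(4.4, 0)), "face_to_face")
  expect_equal(detect_aromatic(base, ring_at(5.0, 90)), "edge_to_face")
  # between the cutoffs with the wrong angle for either class
  expect_equal(detect_aromatic(base, ring_at(4.5, 0)), "none")
  # face-to-face precedence when both criteria hold
  expect_equal(detect_aromatic(base, ring_at(4.0, 0)), "face_to_face")
})

test_that("pi-cation is a symmetric 6.6 Angstrom centroid criterion", {
  expect_true(detect_pi_cation(c(0, 0, 0), c(0, 0, 6.6)))
  expect_false(detect_pi_cation(c(0, 0, 0), c(0, 0, 6.7)))
  # ligand cation against a residue ring: same criterion, reverse direction
  expect_true(detect_pi_cation(c(0, 0, 5.0), c(0, 0, 0)))
})

test_that("build_block counts separate feature instances per cell", {
  # two benzene rings stacked on both faces of a phenylalanine ring
  phe <- residue_template("PHE")
  rg <- sift2d:::residue_rings(phe)[[1]]
  g1 <- sift2d:::ring_coords(rg$centroid + 4.0 * rg$normal, rg$normal)
  g2 <- sift2d:::ring_coords(rg$centroid - 4.0 * rg$normal, rg$normal)
  geom <- list(el = rep("C", 12), xyz = rbind(g1, g2),
               bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(7:12, c(8:12, 7))),
               orders = rep(c(2, 1), 6), charges = integer(12))
  lig <- sift2d:::parse_mol_ligand(sift2d:::mol_block(geom, "double_ring"))
  features <- assign_features(lig)
  expect_equal(sum(vapply(features, `[[`, "", "type") == "R"), 2L)
  block <- build_block(features, phe, ligand = lig)
  expect_equal(block["R", "R"], 2L)
  expect_equal(block["R", "Any"], 2L)
  # no atoms in range: an all-zero block
  far <- make_pair_fixture(fixture_spec("methyl", "LEU", 6.0))
  expect_equal(sum(build_matrix(far$complex)$blocks[[1]]), 0L)
})

test_that("a ligand donor against a backbone acceptor sets (D, A/BB/Any) only", {
  fix <- make_pair_fixture(fixture_spec("hydroxyl_donor", "GLY", 2.0))
  block <- build_matrix(fix$complex)$blocks[[1]]
  expect_equal(block["D", "A"], 1L)
  expect_equal(block["D", "BB"], 1L)
  expect_equal(block["D", "Any"], 1L)
  expect_equal(block["D", "SC"], 0L)
  expect_equal(block["D", "P"], 0L)  # hydrogen bond suppresses polar
})

test_that("cells outside the incrementable mask are always zero", {
  mask <- increment_mask()
  specs <- list(fixture_spec("hydroxyl_donor", "ASN", 2.0),
                fixture_spec("carboxylate", "ARG", 3.2),
                fixture_spec("aromatic_ring", "PHE", 4.0),
                fixture_spec("ammonium", "GLU", 3.2))
  for (s in specs) {
    b <- build_matrix(make_pair_fixture(s)$complex)$blocks[[1]]
    expect_true(all(b[!mask] == 0L), info = s$probe)
    expect_true(all(b >= 0L))
    # row-Any dominance: any specific column nonzero implies Any nonzero
    for (row in rownames(b)) {
      if (any(b[row, -1] > 0)) expect_gt(b[row, "Any"], 0)
    }
  }
})

test_that("the matrix is invariant under rigid-body motion", {
  cx <- make_random_complex(3, probe = "carboxylate", seed = 5)
  m0 <- build_matrix(cx)
  set.seed(99)
  for (i in 1:3) {
    cx2 <- transform_complex(cx, random_rotation(), stats::runif(3, -20, 20))
    m1 <- build_matrix(cx2)
    expect_identical(m1$blocks, m0$blocks)
  }
})

test_that("distance-only detectors are monotone under approach", {
  res <- residue_template("LEU")
  anchor <- sift2d:::anchor_info("methyl", res)
  fired <- FALSE
  for (d in seq(4.0, 1.5, by = -0.25)) {
    now <- detect_contact(matrix(anchor$point + d * anchor$dir, 1), res)$any
    if (fired) expect_true(now, info = paste("d =", d))
    fired <- fired || now
  }
  expect_true(fired)
})

test_that("build_matrix concatenates one block per residue in order", {
  cx <- make_random_complex(2, probe = "methyl", seed = 3)
  m <- build_matrix(cx)
  expect_length(m$blocks, 2L)
  expect_equal(nrow(m$residues), 2L)
  expect_equal(m$residues$seqnum, c(1L, 2L))
  fp <- to_linear(m)
  expect_equal(length(fp$values), sum(increment_mask()) * 2L)
})
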
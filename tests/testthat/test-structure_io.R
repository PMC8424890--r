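test_that("complexes round-trip through the PDB/MOL parsers", {
  pdb <- two_residue_pdb()
  mol <- methanol_mol(shift = c(0, 0, 8))
  cx <- parse_complex(pdb, mol, identifier = "toy")
  expect_s3_class(cx, "sift2d_complex")
  expect_length(cx$residues, 2L)
  expect_equal(vapply(cx$residues, `[[`, "", "name"), c("ALA", "GLY"))
  expect_equal(nrow(cx$ligand$atoms), 6L)  # CH3OH with explicit hydrogens
  expect_equal(sum(!cx$ligand$atoms$is_h), 2L)
  expect_equal(nrow(cx$ligand$bonds), 5L)
})

test_that("waters are excluded and HETATM ligands are selectable by name", {
  het <- sprintf(
    "HETATM  9%02d %-4s CAU A 401      %8.3f%8.3f%8.3f  1.00  0.00           %s",
    1:2, c(" C1", " O1"), c(0, 1.4), c(8, 8), c(0, 0), c("C", "O"))
  cx <- parse_complex(two_residue_pdb(with_water = TRUE, het = het),
                      ligand_selector = "CAU")
  expect_length(cx$residues, 2L)  # the water never becomes a residue
  expect_false(any(vapply(cx$residues, `[[`, "", "name") == "HOH"))
  expect_equal(nrow(cx$ligand$atoms), 2L)
  expect_equal(cx$ligand$source_format, "pdb_het")
  expect_equal(nrow(cx$ligand$bonds), 1L)  # C-O perceived from distance
  # no HETATM residue of that name
  expect_error(parse_complex(two_residue_pdb(het = het),
                             ligand_selector = "XYZ"),
               "ligand-missing")
  # no ligand at all
  expect_error(parse_complex(two_residue_pdb()), "ligand-missing")
})

test_that("residue classification follows the fixed membership table", {
  expect_setequal(classify_residue("PHE"), c("aromatic", "hydrophobic"))
  expect_setequal(classify_residue("ASP"), "negatively_charged")
  expect_setequal(classify_residue("HIS"),
                  c("aromatic", "polar", "positively_charged"))
  expect_setequal(classify_residue("TYR"), c("aromatic", "polar"))
  expect_equal(classify_residue("GLY"), character(0))
  # protonation variants map to the parent residue
  expect_equal(classify_residue("HID"), classify_residue("HIS"))
  expect_warning(out <- classify_residue("XXX"), "unknown residue")
  expect_equal(out, character(0))
  # purity / totality over the standard codes
  for (aa in sift2d:::STANDARD_AA) {
    expect_identical(classify_residue(aa), classify_residue(aa))
  }
})

test_that("backbone/side-chain partition covers every atom exactly once", {
  for (nm in names(sift2d:::SIDECHAIN_ZMAT)) {
    r <- residue_template(nm)
    expect_false(anyNA(r$atoms$region), info = nm)
    expect_true(all(r$atoms$region %in% c("bb", "sc")), info = nm)
    bb_heavy <- r$atoms$name[r$atoms$region == "bb" & !r$atoms$is_h]
    expect_setequal(bb_heavy, c("N", "CA", "C", "O"))
  }
  gly <- residue_template("GLY")
  expect_equal(sum(gly$atoms$region == "sc" & !gly$atoms$is_h), 0L)
  # amide H follows its heavy atom into the backbone
  ser <- residue_template("SER")
  expect_equal(ser$atoms$region[ser$atoms$name == "H"], "bb")
  expect_equal(ser$atoms$region[ser$atoms$name == "HG"], "sc")
  # C-terminal OXT is backbone
  ct <- residue_template("ALA", oxt = TRUE)
  expect_equal(ct$atoms$region[ct$atoms$name == "OXT"], "bb")
})

test_that("generic-number annotation labels matching residues only", {
  cx <- parse_complex(two_residue_pdb(), methanol_mol(c(0, 0, 8)))
  ann <- tibble::tibble(chain = "A", seqnum = 1L, generic_number = "3x32")
  cx2 <- attach_generic_numbers(cx, ann)
  expect_equal(cx2$residues[[1]]$generic_number, "3x32")
  expect_true(is.na(cx2$residues[[2]]$generic_number))
  # empty annotation leaves the complex unchanged
  expect_identical(attach_generic_numbers(cx, ann[0, ]), cx)
  # stale key: warning, nothing dropped
  stale <- tibble::tibble(chain = "A", seqnum = c(1L, 99L),
                          generic_number = c("3x32", "9x99"))
  expect_warning(cx3 <- attach_generic_numbers(cx, stale), "no residue")
  expect_length(cx3$residues, 2L)
  # Ballesteros-Weinstein dotted labels are normalized textually
  bw <- tibble::tibble(chain = "A", seqnum = 2L, generic_number = "7.38")
  expect_equal(attach_generic_numbers(cx, bw)$residues[[2]]$generic_number,
               "7x38")
  # duplicate keys refused
  dup <- tibble::tibble(chain = "A", seqnum = c(1L, 1L),
                        generic_number = c("3x32", "3x33"))
  expect_error(attach_generic_numbers(cx, dup), "unique")
})

test_that("parsing is order-stable", {
  pdb <- two_residue_pdb()
  mol <- methanol_mol(c(0, 0, 8))
  a <- parse_complex(pdb, mol)
  b <- parse_complex(pdb, mol)
  expect_identical(lapply(a$residues, `[[`, "atoms"),
                   lapply(b$residues, `[[`, "atoms"))
  expect_identical(a$ligand$atoms, b$ligand$atoms)
})
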
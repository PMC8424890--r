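# Thin wrapper around the OpenBabel SWIG bindings shipped inside ChemmineOB.
# Only three capabilities are used: reading a molecule block, SMARTS matching
# with atom-index maps, and per-atom formal charges. The bindings are internal
# to ChemmineOB, so they are fetched from its namespace in one place here.

ob_fun <- function(name) {
  get(name, envir = getNamespace("ChemmineOB"))
}

# parse an SDF/MOL or PDB text block into an OBMol handle
ob_read <- function(text, format = c("mol", "sdf", "pdb")) {
  format <- match.arg(format)
  if (format == "mol") format <- "sdf"
  conv <- ob_fun("OBConversion")()
  ob_fun("OBConversion_SetInFormat")(conv, format)
  mol <- ob_fun("OBMol")()
  ok <- ob_fun("OBConversion_ReadString")(conv, mol, paste(text, collapse = "\n"))
  if (!isTRUE(ok) || ob_fun("OBMol_NumAtoms")(mol) == 0) {
    stop("OpenBabel could not parse the ", format, " block", call. = FALSE)
  }
  mol
}

# unique SMARTS matches as a list of 1-based atom index vectors
ob_smarts_match <- function(mol, smarts) {
  pat <- ob_fun("OBSmartsPattern")()
  if (!isTRUE(ob_fun("OBSmartsPattern_Init")(pat, smarts))) {
    stop("unparsable SMARTS pattern: ", smarts, call. = FALSE)
  }
  if (!isTRUE(ob_fun("OBSmartsPattern_Match")(pat, mol))) return(list())
  maps <- ob_fun("OBSmartsPattern_GetUMapList")(pat)
  lapply(maps, as.integer)
}

ob_formal_charges <- function(mol) {
  n <- ob_fun("OBMol_NumAtoms")(mol)
  getat <- ob_fun("OBMol_GetAtom")
  getq <- ob_fun("OBAtom_GetFormalCharge")
  vapply(seq_len(n), function(i) as.integer(getq(getat(mol, i))), integer(1))
}

ob_element <- function(mol) {
  n <- ob_fun("OBMol_NumAtoms")(mol)
  getat <- ob_fun("OBMol_GetAtom")
  getz <- ob_fun("OBAtom_GetAtomicNum")
  z <- vapply(seq_len(n), function(i) as.integer(getz(getat(mol, i))), integer(1))
  PERIODIC_SYMBOLS[z]
}

PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)
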
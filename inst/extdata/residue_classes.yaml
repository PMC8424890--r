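# Interaction-capability classes of the standard amino acids.
# Classes are not exclusive (TYR is aromatic and polar). Users may supply a
# modified copy via classify_residue(table = ...) / the --config class_table
# key. Charged residues are handled by the dedicated charged detector and are
# deliberately not listed under `polar`.
aromatic: [PHE, TYR, TRP, HIS]
hydrophobic: [ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, CYS]
polar: [SER, THR, ASN, GLN, TYR, HIS, CYS, TRP]
negatively_charged: [ASP, GLU]
positively_charged: [LYS, ARG, HIS]
# residue-name aliases (protonation / tautomer variants) mapped before lookup
aliases:
  HID: HIS
  HIE: HIS
  HIP: HIS
  HSD: HIS
  HSE: HIS
  HSP: HIS
  CYX: CYS
  ASH: ASP
  GLH: GLU
  LYN: LYS
  ARN: ARG
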
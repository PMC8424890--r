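# Default ligand pharmacophore feature definitions (OpenBabel SMARTS dialect).
#
# Six explicit feature types; the seventh descriptor row (vdW, "any atom") is
# not a SMARTS feature: every ligand heavy atom carries it implicitly.
#
# Each entry: name, smarts, and optionally `members` — 1-based positions
# within the SMARTS atom order that become the feature's member atoms
# (default: all matched atoms). Within one type, a match whose atom set is a
# subset of another match's atom set is absorbed into the larger match.
#
# `cluster: true` (hydrophobic) merges connected matched atoms into a single
# feature per contiguous apolar fragment. Aromatic matches each yield one
# feature per smallest aromatic ring.
acceptor:
  patterns:
    - name: carbonyl_oxygen
      smarts: "[OX1+0]"
    - name: hydroxyl_or_ether_oxygen
      smarts: "[OX2+0]"
    - name: oxyanion
      smarts: "[OX1-]"
    - name: aromatic_nitrogen
      smarts: "[nX2+0]"
    - name: imine_nitrogen
      smarts: "[NX2+0]"
    - name: nitrile_nitrogen
      smarts: "[NX1+0]"
    - name: amine_nitrogen
      smarts: "[NX3+0;!$([NX3+0][#6X3]=[#7,#8,#16]);!$([NX3+0]a)]"
donor:
  patterns:
    - name: nitrogen_with_h
      smarts: "[#7;!H0]"
    - name: oxygen_with_h
      smarts: "[OX2;!H0]"
    - name: thiol
      smarts: "[#16X2;!H0]"
negative:
  patterns:
    - name: carboxylate
      smarts: "[CX3](=[OX1])[OX1-,OX2H1]"
      members: [2, 3]
    - name: sulfo_phospho_anion
      smarts: "[SX4,PX4](=[OX1])[OX1-]"
      members: [2, 3]
    - name: formal_anion
      smarts: "[-1,-2]"
positive:
  patterns:
    - name: guanidinium
      smarts: "[NX3][CX3](=[NX2,NX3+])[NX3]"
      members: [1, 2, 3, 4]
    - name: formal_cation
      smarts: "[+1,+2;!$([*+1]~[OX1-])]"
    - name: ionizable_amine
      smarts: "[NX3+0;!$([NX3+0][#6X3]=[#7,#8,#16]);!$([NX3+0]a)]"
hydrophobic:
  cluster: true
  patterns:
    - name: apolar_carbon
      smarts: "[#6+0;!a;!$([#6]~[!#6;!#1])]"
aromatic:
  patterns:
    - name: six_ring
      smarts: "a1aaaaa1"
    - name: five_ring
      smarts: "a1aaaa1"
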
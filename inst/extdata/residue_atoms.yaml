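# Side-chain functional-atom tables used by the interaction detectors.
# Backbone contributions are implicit for every residue: amide N is a donor,
# carbonyl O (and terminal OXT) are acceptors.
# rings: atom-name lists of each aromatic ring (used for stacking/pi-cation);
# charged: the formally charged group; donors/acceptors: H-bond capable heavy
# atoms; polar: targets of the distance-only polar contact.
ASP: {charged: [OD1, OD2], acceptors: [OD1, OD2]}
GLU: {charged: [OE1, OE2], acceptors: [OE1, OE2]}
LYS: {charged: [NZ], donors: [NZ]}
ARG: {charged: [CZ, NE, NH1, NH2], donors: [NE, NH1, NH2]}
HIS:
  charged: [ND1, NE2]
  donors: [ND1, NE2]
  acceptors: [ND1, NE2]
  polar: [ND1, NE2]
  rings: [[CG, ND1, CE1, NE2, CD2]]
PHE: {rings: [[CG, CD1, CD2, CE1, CE2, CZ]]}
TYR:
  rings: [[CG, CD1, CD2, CE1, CE2, CZ]]
  donors: [OH]
  acceptors: [OH]
  polar: [OH]
TRP:
  rings: [[CG, CD1, NE1, CE2, CD2], [CD2, CE2, CZ2, CH2, CZ3, CE3]]
  donors: [NE1]
  polar: [NE1]
SER: {donors: [OG], acceptors: [OG], polar: [OG]}
THR: {donors: [OG1], acceptors: [OG1], polar: [OG1]}
ASN: {donors: [ND2], acceptors: [OD1], polar: [OD1, ND2]}
GLN: {donors: [NE2], acceptors: [OE1], polar: [OE1, NE2]}
CYS: {donors: [SG], polar: [SG]}
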
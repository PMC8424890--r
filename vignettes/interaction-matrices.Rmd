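---
title: "Interaction matrices: the model behind sift2d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction matrices: the model behind sift2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sift2d)
```

## The descriptor

A two-dimensional structural interaction fingerprint describes a
protein–ligand complex one residue at a time. For residue *i* the descriptor
holds a 7 × 9 matrix of non-negative counts: rows index the ligand's
pharmacophore feature types (acceptor A, donor D, hydrophobe H, negative N,
positive P, aromatic R, and the wildcard vdW row meaning "any ligand atom"),
columns index interaction types (Any, backbone BB, side chain SC, polar P,
hydrophobic H, residue-acceptor A, residue-donor D, charged C, aromatic R).
Counts, not bits: two ligand aromatic rings stacking with one phenylalanine
give (R, R) = 2, because each distinct feature instance increments a cell
once. Blocks concatenated in residue order give a 7 × (9·N) matrix.

Not every (row, column) pair is chemically meaningful. A boolean
*incrementable mask* (shipped as `increment_mask()`, a user-replaceable CSV)
fixes which cells can ever be set: the acceptor row can mark the
residue-donor column but not the residue-acceptor column; charged rows are
restricted to side chains, because backbones are not formally charged
(chain termini are deliberately not treated as charged groups); the
wildcard row only records the region columns Any/BB/SC. Cells outside the
mask are structurally zero, and the 1D linearization enumerates exactly the
masked-in cells.

## Feature perception

Ligand features are assigned by SMARTS matching with the OpenBabel engine,
from an editable YAML pattern file (`read_feature_defs()`). Conventions:

* matches with identical atom sets are merged, and a match whose atom set is
  strictly contained in another match of the same type is absorbed by it —
  so acetate yields one negative feature spanning both carboxylate oxygens,
  not an extra single-oxygen feature from the formal-charge pattern;
* each smallest aromatic ring is one R feature (naphthalene has two);
* contiguous apolar carbons merge into a single hydrophobic feature per
  fragment;
* hydrogens are never feature members; donor hydrogens enter only through
  the hydrogen-bond geometry;
* the vdW row is evaluated per ligand heavy atom rather than as a
  whole-ligand centroid feature, and increments each region column at most
  once per residue — the classical "any contact" semantics;
* feature centroids are unweighted means of the member heavy atoms; for
  charged groups the members are the charged atoms themselves (both
  carboxylate oxygens; the guanidinium carbon plus nitrogens).

## Geometric criteria and their conventions

All cutoffs are *inclusive* and exposed in `geometry_params()`:

| criterion | default | unit |
|---|---|---|
| contact (vdW/hydrophobic/charged/polar) | 3.5 | Å |
| hydrogen bond H···X distance | 2.8 | Å |
| donor angular deviation | 120 | degrees |
| acceptor angular deviation | 90 | degrees |
| face-to-face centroid distance | 4.4 | Å |
| edge-to-face centroid distance | 5.5 | Å |
| π-cation centroid distance | 6.6 | Å |
| face-to-face max interplanar angle | 30 | degrees |
| edge-to-face min interplanar angle | 60 | degrees |

Two conventions deserve emphasis because the customary phrasing of
hydrogen-bond angle limits is ambiguous:

1. **Distance reference.** The 2.8 Å limit is measured between the donor
   *hydrogen* and the acceptor heavy atom (`hbond_dist_mode = "hx"`): in the
   Y–H···X notation, the contact dots sit between H and X. A heavy-atom
   (Y···X) mode is provided for users who prefer the other reading.
2. **Angle reference.** Both angle limits are read as maximum permitted
   *deviations from ideal geometry*: donor deviation = 180° − ∠(Y,H,X)
   (0° for a perfectly linear bond), acceptor deviation =
   180° − ∠(H,X,antecedent direction), where the antecedent direction is
   the mean unit vector from X to its bonded heavy neighbours. This is the
   only reading under which 120° and 90° both act as upper bounds on a
   quantity that is zero in the ideal case. Both are configurable.

The interplanar angle between ring planes is always folded to [0°, 90°];
ring normals come from a least-squares plane fit (smallest principal axis)
and their sign is irrelevant. Face-to-face takes precedence when both
stacking classes hold geometrically. π-cation detection is distance-only —
no angle criterion — and runs in both directions: a ligand ring near a
residue cation increments the R row, a ligand cation near a residue ring
the P row, both in the aromatic column.

Redundancy rules keep one physical contact from being double-counted: a
feature instance increments any given cell at most once per residue; a
fired hydrogen bond suppresses the distance-only polar column for that
feature–residue pair; the vdW row counts regions, not atoms.

A `boundary_eps` guard (10⁻⁶ Å / degrees) makes all comparisons robust to
floating-point noise, so rigid-body rotation of a complex never flips a
detector — this is asserted as a test invariant.

## Residue-side tables

Residues are classified (aromatic, hydrophobic, polar, negatively and
positively charged; not mutually exclusive) by a fixed, user-replaceable
table. Charged residues (ASP, GLU, LYS, ARG) are *not* additionally listed
as polar: their side-chain contacts are captured by the dedicated charged
detector, and listing them under polar too would double-code the same
physical contact into two columns. HIS defaults to aromatic + polar +
positively charged — its charge state is structure-dependent and the table
is a config override away. GLY carries no class: a lone CA makes a steric
contact (vdW row) but is not treated as a hydrophobic surface.

Side-chain functional atoms (H-bond donors/acceptors, charged groups,
aromatic ring atoms, polar targets) are tabulated per residue type in an
editable YAML file; backbone N (donor) and O/OXT (acceptors) apply to every
residue. Hydrophobic contacts target side-chain carbon/sulfur atoms only —
consequently the backbone column of the H row, while legal under the mask,
is never set by the default rules.

Hydrogens are expected on the input structure (the descriptor was designed
for prepared complexes). When a donor carries no resolvable hydrogen the
hydrogen-bond test degrades to a heavy-atom distance criterion at the
contact cutoff, and `parse_complex()` warns; the complex records
`hydrogens_present` so downstream users can tell the two regimes apart.

## Profiles, frequencies, hotspots

A collection of matrices aligned on a common position axis (generic residue
numbers such as `3x32`; the axis is the sorted union, and positions a
receptor does not cover are zero blocks flagged *absent*, distinct from an
observed zero) can be averaged into a profile. Averaging divides, by
default, by the total number of matrices (`all_matrices`): a position
absent from a receptor counts as non-interacting, which matches reading a
contact fraction "across the investigated dataset". A `present_only` mode
divides by the number of matrices actually covering the position, for
collections with very heterogeneous coverage. After averaging, cells
*strictly below* the silencing threshold (default 0.3) are set to zero —
a cell at exactly 0.3 (set in 3 of 10 complexes) survives. Hotspot
selection is the complementary strict inequality: a position qualifies when
its contact fraction is *strictly greater* than the cutoff (default 0.30),
so exactly 30 % is excluded. Both strictness choices follow the method's
wording ("lower than" silenced; "more than 30 %" kept) and are asserted at
the boundary in the tests.

Generic-number sorting treats the first two digits of the position as the
primary key and any further digit as a bulge suffix, so `5x461` sorts
between `5x46` and `5x47`. Ballesteros–Weinstein labels ("5.46") are
normalized textually to `5x46` on input; any *positional* renumbering
between the two schemes must be encoded in the user's annotation table —
the package never converts arithmetically, because bulges shift the
correspondence.

Differential profiles classify each position as common or unique to either
collection (after silencing) and report signed cell differences; outlier
ranking measures each complex's Euclidean distance from the profile in
count-fingerprint space, ties broken by complex id for reproducibility.
Tanimoto similarity of two all-zero binary fingerprints is defined as 1.0
(two complexes with no detected interactions are identical, not maximally
different); this convention is documented rather than universal.

## The synthetic-fixture generator

Every numeric claim in the test suite is grounded in synthetic complexes
with analytically known descriptors. Residue templates are built from
idealized internal coordinates (standard bond lengths and angles, amide
hydrogens present, polar side-chain hydrogens where donors need them), so a
probe placed "2.0 Å from the OD1 lone-pair axis" has exact, hand-checkable
geometry. Six probes cover the feature rows: methane (hydrophobe), benzene
(ring), methylammonium (+1), acetate (−1), methanol (donor+acceptor),
acetone (acceptor). The fixture module derives the expected 7 × 9 block by
a straight-line re-implementation of the rules applied directly to the
coordinates — independent of the SMARTS engine and the detector code — and
the equivalence of the two paths on fixtures, random multi-residue
complexes (200 in the acceptance suite) and jittered collections is itself
the central oracle test.

Collections with known means jitter the probe rigidly and verify a guard:
the expected block must be invariant when every distance cutoff shifts by
±0.1 Å and every angle cutoff by ±1° — if the jitter could bring any
quantity within the margin of a boundary, the generator refuses. Boundary
sweeps (`boundary_sweep()`) probe each criterion on a 0.01 Å / 0.1° grid;
these reproduce all nine defaults exactly and are what
`scripts/acceptance.R` reports.

What the fixtures deliberately do not emulate: conformational strain,
crystallographic disorder, water-mediated bridges, metal sites, multiple
ligand copies, and realistic packing density. Passing tests therefore
demonstrate the correctness of the descriptor calculus on well-formed
input, not robustness to pathological crystallography; the published GPCR
case studies additionally require externally curated, commercially prepared
structures and are out of the test scope.

## Numerical and design choices

* **Boundary inclusivity**: every "no greater than"/"must not exceed" is
  `≤` (and `≥` for the edge-to-face minimum angle); the sweeps pin this.
* **Alternate locations**: the highest-occupancy conformer is kept — the
  descriptor is single-conformer by design.
* **PDB-only ligands**: bonds are perceived by covalent-radius distance
  criteria (sum of radii + 0.45 Å); SDF/MOL input is preferred because it
  carries bond orders and formal charges.
* **Acceptors without heavy neighbours** (isolated ions) skip the
  acceptor-angle test rather than failing it.
* **Empty fingerprint comparison**: Tanimoto 1.0 (above).
* **Problem sizes**: the shipped tests run on 1–5-residue synthetic
  complexes, 200-fixture random batches and 10–100-matrix collections —
  sizes at which expected outcomes are provable by construction while the
  whole suite completes in well under a minute per module.
* **Serialization**: versioned JSON with a parameter fingerprint (a small
  deterministic hash of the geometry parameters and mask). Operations that
  combine matrices refuse mismatched fingerprints instead of silently
  mixing incompatible descriptors.

## Known limitations

Halogen bonds, metal coordination, water bridges and salt-bridge strength
are not modelled. Aromaticity of PDB-only ligands depends on OpenBabel's
perception. The residue class and atom tables cover the 20 standard amino
acids plus common protonation-variant aliases; exotic residues contribute
only steric (vdW-row) contacts, with a warning. Backbone hydrogen-bond
geometry at chain termini uses the same donor/acceptor rules as internal
residues.
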
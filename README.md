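# sift2d — two-dimensional structural interaction fingerprints

Classical structural interaction fingerprints (SIFts) encode a
protein–ligand complex residue by residue: a fixed-length bit stretch per
binding-site residue records which interaction types the ligand forms with
it. The ligand itself is treated as a featureless blob — the fingerprint
says *that* a residue is hydrogen-bonded, but not *which chemistry of the
ligand* does the bonding.

`sift2d` implements the two-dimensional extension of that idea. Each residue
is described by a **7 × 9 count matrix**: the rows are the ligand's
pharmacophore feature types and the columns the interaction types,

| rows (ligand features)   | columns (interaction types)  |
|--------------------------|------------------------------|
| **A** H-bond acceptor    | **Any** any interaction      |
| **D** H-bond donor       | **BB** with the backbone     |
| **H** hydrophobe         | **SC** with the side chain   |
| **N** negatively charged | **P** polar                  |
| **P** positively charged | **H** hydrophobic            |
| **R** aromatic ring      | **A** residue is acceptor    |
| **vdW** any atom         | **D** residue is donor       |
|                          | **C** charged                |
|                          | **R** aromatic               |

so a cell such as (R, R) = 2 reads "two distinct ligand aromatic rings
stack with this residue". Per-residue blocks concatenated along the
sequence give the full descriptor, a matrix of 7 × (9·N) fields for N
residues. Only a fixed subset of cells is chemically meaningful (the
*incrementable mask*, e.g. a ligand donor row can set the residue-acceptor
column but not the residue-donor column); everything outside the mask is
structurally zero.

Ligand features are perceived by SMARTS matching (OpenBabel engine, editable
pattern file). Interactions are detected by explicit geometric criteria, all
cutoffs inclusive:

* van der Waals / hydrophobic / charged / polar contact: minimum heavy-atom
  distance ≤ **3.5 Å**, with feature–residue complementarity;
* hydrogen bond (Y–H···X): d(H, X) ≤ **2.8 Å**, donor deviation from
  linearity 180° − ∠(Y,H,X) ≤ **120°**, acceptor deviation
  180° − ∠(H,X,antecedent) ≤ **90°**;
* aromatic stacking, centroid–centroid: face-to-face ≤ **4.4 Å** with
  interplanar angle ≤ **30°**; edge-to-face ≤ **5.5 Å** with angle ≥ **60°**;
* π-cation: ring centroid to charged-group centroid ≤ **6.6 Å**
  (distance only, both directions).

On top of the per-complex descriptor the package provides: alignment of
matrices from different receptors on **generic residue numbers** (GPCRdb
style, `3x32`); **interaction profiles** — cell-wise averages with values
below a silencing threshold (default 0.3) set to zero; **contact
frequencies and hotspots** (positions interacting in more than a given
fraction of the structures, default 30 %); **differential profiles** (e.g.
agonist vs antagonist consensus); outlier ranking; **1D linearization** to
binary or count fingerprints with **Tanimoto** and **Euclidean** comparison;
gray-scale and red/blue heat maps; and a synthetic-fixture generator that
builds toy complexes whose descriptors are known analytically — the basis
of the test suite, which needs no external structures.

Intended users: structural bioinformaticians and computational medicinal
chemists comparing binding modes across crystal structures or docking poses,
particularly for receptor families with a shared generic numbering scheme
(GPCRs).

## Worked example

```r
library(sift2d)

# a methanol donor probe placed 2.0 Angstrom (H...O) from an asparagine
fix <- make_pair_fixture(fixture_spec("hydroxyl_donor", "ASN", 2.0))
cx  <- attach_generic_numbers(fix$complex,
         tibble::tibble(chain = "A", seqnum = 1L, generic_number = "5x46"))
m <- build_matrix(cx)
m$blocks[[1]]
#>     Any BB SC P H A D C R
#> A     1  0  1 1 0 0 0 0 0
#> D     1  0  1 0 0 1 0 0 0
#> H     0  0  0 0 0 0 0 0 0
#> N     0  0  0 0 0 0 0 0 0
#> P     0  0  0 0 0 0 0 0 0
#> R     0  0  0 0 0 0 0 0 0
#> vdW   1  0  1 0 0 0 0 0 0
```

Reading the block: the methanol hydroxyl donates a hydrogen bond to the
side-chain carbonyl of ASN — row D sets the residue-acceptor column A, the
side-chain column SC and Any. The same oxygen is also an acceptor near a
polar side chain, so row A sets the polar column P (the acceptor-side
hydrogen-bond geometry to ND2 does not hold, hence no (A, D) cell); and any
heavy atom within contact range sets the vdW row.

Profiles average collections and silence noise — a cell set in 3 of 10
matrices survives at the 0.3 threshold, one set in 2 of 10 is silenced:

```r
coll <- make_collection(10,
  c(rep(list(fixture_spec("ammonium", "ASP", 3.3)), 3),
    rep(list(fixture_spec("ammonium", "ASP", 6.0)), 7)), seed = 1)
prof <- average_profile(coll)            # threshold 0.3
prof$blocks[[1]]["P", c("Any", "SC", "C")]
#> Any  SC   C
#> 0.3 0.3 0.3

fp <- to_linear(m, binary = TRUE)
fp
#> <sift2d binary fingerprint: length 29, 8 set positions>
tanimoto(fp, fp)
#> [1] 1
```

The command line mirrors the library (`exec/sift2d` after installation):

```sh
sift2d compute --pdb complex.pdb --ligand ligand.mol \
       --annotation generic_numbers.csv --out matrix.json
sift2d profile --out profile.json matrices/*.json
sift2d hotspots --out hotspots.csv --min-fraction 0.30 matrices/*.json
sift2d heatmap --in profile.json --out profile.png
```

## Scope notes

The package expects protonated input structures (hydrogens present); without
hydrogens it falls back to distance-only hydrogen-bond detection and says
so. Protonation assignment, structure preparation, docking, mmCIF input and
nucleic acids are out of scope. The published GPCR case-study numbers
(hotspot lists across curated class A crystal structures) require externally
curated and commercially prepared structures and are not reproduced by the
test suite; the machinery to attempt them (`align_by_generic`,
`contact_frequency`, `hotspots`, `differential_profile`) is fully exercised
on synthetic collections instead.
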
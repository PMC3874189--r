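---
title: "Adenosine recognition by CCCH zinc finger arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adenosine recognition by CCCH zinc finger arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAcode)
```

## The recognition problem

Nab2-family proteins (ZC3H14 in humans) regulate poly(A) tail length and
mRNP packaging by binding polyadenosine RNA through a tandem array of CCCH
zinc fingers. Each finger coordinates one Zn²⁺ through three cysteines and
a histidine and presents a shallow groove in which an adenine base sits
stacked against an aromatic side chain, often with the aliphatic face of a
lysine or arginine on the other side. Specificity for adenine over the
other bases comes from a small hydrogen-bond grammar:

* the exocyclic **N6 amine donates** a hydrogen bond to the **SG sulfur of
  a Zn-coordinated cysteine** — the thiolate has lost its own proton to
  Zn²⁺ binding and can only accept, so a donor is required at the purine
  6-position;
* a neighbouring **backbone amide** reads a ring acceptor: **N1** when the
  base faces the Zn cluster with its Watson–Crick edge, **N7** when it
  presents its Hoogsteen edge;
* guanine offers the acceptor O6 instead of a donor and is excluded;
  cytosine retains a donor (N4) but has no N7 and loses the second bond
  (weak binding); uracil behaves like guanine.

Because the stacking platforms occupy fixed motif positions — two residues
after the first cysteine and two residues after the third — the number of
adenosines a finger binds (0, 1 or 2) is predictable from sequence alone.
This "code" is the heart of the package: two aromatic code positions
predict two bound adenosines, exactly one predicts one, neither predicts
none. Arrays sum their fingers, so a (2,1,2) three-finger module reads
five key adenosines even though it spans about eight nucleotides; the
remaining positions are spacers whose base identity is not read. That is
also why the transcript scanner looks for *A-rich windows*, not only
homopolymer runs.

## Finger detection

`detect_ccch_fingers()` matches `C-x(a..b)-C-x(c..d)-C-x(e)-H`. The
spacing bounds are a genuinely open design choice — the motif literature
quotes fingers with a range of loop lengths — and we fixed
`C-x(4..8)-C-x(4..6)-C-x(3)-H` as a bracket that covers both Nab2-class
and TIS11d-class fingers. Overlapping candidates are resolved greedily
left-to-right, preferring the shortest total loop and resuming after the
matched histidine. This mirrors how tandem arrays are laid out and makes
the scan deterministic; the test suite proves it equivalent to brute-force
enumeration of all candidate tuples over a hundred random sequences.

The aromatic code set is \{F, Y, W\} (tryptophan included as chemically
equivalent, although the known structures only exhibit Phe/Tyr) and the
basic set \{K, R\}. An `X` at a code position counts as neither. One known
array member (the first finger of the *S. cerevisiae* protein) binds two
adenosines without fitting the consensus; its layout — leucine directly
after the first cysteine together with a histidine two after the third —
is implemented as an optional exception rule (`leu_his_exception`,
default on). The finger-internal numbering convention behind that
published observation is ambiguous; "Leu at c1+1 with His at c3+2" is this
package's fixed interpretation, and the rule can be disabled.

## Contact grammar in 3D

Crystal structures of finger/poly(A) complexes are solved without
hydrogens at typical resolutions, so all geometric criteria are
heavy-atom criteria. None of the thresholds below is dictated by a single
source; they are standard crystallographic practice, fixed once in
`default_config()` and configurable:

| criterion | default | notes |
|---|---|---|
| H-bond donor–acceptor | ≤ 3.5 Å (≤ 3.9 Å to S) | plus acceptor–donor–antecedent angle ≥ 90° when the antecedent atom is modelled |
| stacking | centroid ≤ 4.5 Å, interplanar ≤ 30°, lateral offset ≤ 2.5 Å | purines use the six-membered ring; Trp contributes both rings; offset taken against both normals (symmetric) |
| cation–π | cation ≤ 6.0 Å of centroid, axial angle ≤ 45° | cation points: Lys NZ, Arg CZ; failing geometries within 9 Å retained for reporting |
| Zn ligands | S ≤ 2.6 Å, N ≤ 2.5 Å | a cysteine is "Zn-coordinating" iff its SG is a ligand of some site |
| edge call | margin 0.5 Å | Watson–Crick iff d(N1,Zn) < d(N7,Zn) − margin; Hoogsteen for the reverse; indeterminate within the margin |

The `N6->SG_ZnCys` hydrogen-bond category is only assigned when the
acceptor sulfur belongs to a detected Zn site — the chemical argument
above depends on the thiolate state. Published descriptions of one bound
base are internally inconsistent about whether its carbonyl contact is
made through N6 or N7; the detectors deliberately report whatever the
geometry supports (the N7-to-carbonyl variant falls in the `other`
category) rather than hard-coding either reading.

`build_fingerprint()` assigns each contacted adenosine to the finger
contributing its stacking aromatic, falling back to the finger with most
contact atoms, then tallies per-finger counts, edge orientations and the
buried interface area.

## Surface areas

`compute_sasa()` is a Shrake–Rupley implementation with a deterministic
golden-spiral point set — no random sphere sampling, so identical inputs
give bit-identical totals. The van der Waals radii are fixed and
documented (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Zn 1.39, Mg 1.73 Å;
probe 1.4 Å; 960 points per atom by default). For a single atom every
spiral point is accessible, so the analytic sphere 4π(r+p)² is reproduced
exactly; for overlapping pairs the test suite checks the spherical-cap
closed form to 2%. Buried area is the standard
SASA(A) + SASA(B) − SASA(A∪B). Because the published interface-area
protocol (software and atom grouping) is unstated, the RNA group defaults
to nucleotides with any atom within 4.5 Å of the protein group, and
comparisons against published interface areas should carry a ±10%
tolerance. Note that a fixed world-oriented point set means areas are
deterministic but only rotationally invariant to within the point-set
resolution (≈1% at 960 points).

## Superposition and domain rotation

`superpose()` is the Kabsch SVD solution with the determinant correction
that forbids reflections; degenerate (collinear) inputs are rejected. The
independent cross-check in the tests is a quaternion eigenvector method,
which must agree to 10⁻⁸ Å RMSD. `domain_rotation_angle()` reproduces the
classic two-step analysis of hinge motion between homologous structures:
superpose on an anchor selection (e.g. the terminal fingers), then
measure the residual rotation of a mobile selection (the middle finger)
from the rotation-matrix trace. The quantity is invariant to any global
rigid motion of either model, which the tests verify, and a planted
53° rotation is recovered to 0.1°.

## Transcript scanning

A finger array with per-finger stoichiometries summing to K and footprint
span S defines the window rule: report every S-nucleotide window holding
at least K adenosines (0-based, half-open coordinates). S defaults to 8
for a three-finger array — the documented case of a three-finger module
covering eight nucleotides — and to K + (n_fingers − 1) otherwise, one
spacer per inter-finger gap; no general span rule is established, so both
are config-overridable. Scoring is a bare adenosine count capped at K: no
positional weighting exists to justify anything richer, and whether the
spacers must fall at specific positions is unresolved, so windowed
counting is the neutral choice. Scanning is single-stranded (mRNA
semantics), case- and T/U-insensitive. `find_exact_motif()` handles
literal motifs such as the co-immunoprecipitation consensus
`AAAAAAAAAAAG`, and `poly_a_runs()` reports maximal homopolymer runs for
tail detection.

## Masses

`rna_mass()` uses average-isotopic chain-residue masses (A 329.21,
C 305.18, G 345.21, U 306.17 Da); a free 5′-OH/3′-OH oligonucleotide
carries one fewer phosphate than residues, hence
M = Σresidues − 79.98 + 18.02. The hydroxyl convention is the default
because synthetic oligonucleotides are supplied that way (a 5′-phosphate
would add 79.98 Da). Protein masses are sums of average residue masses
plus one water. `complex_mass()` reports unrounded sums — kDa rounding to
one decimal happens only at print time, which is why a printed
"7.7 + 2.6" can appear as 10.2 or 10.3 depending on where rounding is
applied.

```{r mass}
rna_mass("AAAAAAAA")
```

## What the synthetic fixtures do and do not show

The generators are first-class, seeded code
(`withr::with_seed`; same spec + seed ⇒ byte-identical output):

* `make_finger_sequence()` / `make_finger_array()` emit sequences whose
  code features match a requested class exactly, using a neutral filler
  alphabet that cannot create spurious motifs or features;
* `make_contact_fixture()` realises each contact category as a minimal
  atom set with exact distances/angles, built from planar canonical ring
  templates (regular 1.39 Å hexagon, pentagon fused on the C4–C5 edge,
  N6 at 1.34 Å), optionally with out-of-threshold decoys;
* `make_mini_complex()` assembles per-finger binding modules — Zn site,
  stacking platform, N6→SG bond, edge-appropriate amide, cation over the
  opposite face — 30 Å apart with randomised orientations, and returns
  the planted inventory as ground truth;
* `make_transcript()` plants literal motifs in i.i.d. background.

These fixtures are *idealised*: planar bases, no ribose-phosphate
backbone, no thermal disorder, no alternate conformations, no solvent
except where a bridge is planted, and geometry placed exactly at or away
from thresholds. Passing tests therefore demonstrate that the detectors
implement their stated geometric definitions and recover planted truth
with zero false positives — they do not demonstrate robustness to real
crystallographic noise, missing atoms, or non-ideal stacking geometries,
which should be assessed on deposited structures. The structure pipeline
accepts any PDB-format file (model 1, altloc A) for exactly that purpose.

```{r complex}
mc <- make_mini_complex(c(2, 1, 2), seed = 1)
build_fingerprint(mc$model, mc$fingers)
```

## Numerical choices and problem sizes

Ties and degenerate inputs are handled explicitly: motif overlaps resolve
greedily with shortest-total-loop preference (ties by earlier second,
then third cysteine); edge calls inside the 0.5 Å margin are
`indeterminate`, never forced; buried areas are clamped at zero;
reflection is never accepted as a superposition; empty sequences, invalid
alphabets, overlapping area groups and collinear point sets raise domain
errors rather than returning numbers.

The default test suite runs the property checks at sizes chosen to be
decisive yet quick: scanner-vs-oracle equivalence on 100 random sequences
(length ≤ 500) and 100 random transcripts (length 1000), rigid-motion
invariance over 50 random frames, Kabsch-vs-quaternion agreement over 20
instances, and SASA at 60–960 sphere points. The whole suite completes in
well under a minute on a single core.

## Known limitations

* Sequence-level calls are per-finger and ignore inter-finger context; no
  multiple-sequence alignment, profile search or affinity prediction is
  attempted, and the code's stoichiometry is a structural capacity, not a
  measured occupancy.
* PDB input only (no mmCIF); model 1 and altloc A are fixed policy.
* SASA is O(atoms × neighbours × points) in plain R — comfortable for
  finger-sized complexes (hundreds of atoms), not tuned for ribosomes.
* The footprint scanner models neither avidity nor the tethering of
  remote A-rich clusters; it enumerates candidate windows and leaves
  ranking to the user.
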
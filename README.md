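# polyAcode

Tools for analysing how tandem **CCCH zinc finger** proteins of the
Nab2/ZC3H14 family recognise **polyadenosine RNA**, for structural
bioinformaticians and RNA biologists working on poly(A) tail regulation
and mRNP packaging.

Each CCCH finger (`C-x(4..8)-C-x(4..6)-C-x(3)-H`) buries an adenine in a
surface groove: the base stacks on an aromatic side chain and is read by
hydrogen bonds — the adenine **N6 amine donates to the SG of a
Zn-coordinated cysteine** (the thiolate can only accept, so guanine's O6
is excluded), while a neighbouring **backbone amide reads N1**
(Watson–Crick edge in) **or N7** (Hoogsteen edge in). The aromatic
platforms sit at fixed motif positions — two residues after the first and
third cysteine — so a finger's adenosine stoichiometry follows a sequence
code:

| aromatic at c1+2 | aromatic at c3+2 | adenosines bound |
|---|---|---|
| yes | yes | 2 |
| yes or no (exactly one) | | 1 |
| no | no | 0 |

An array sums its fingers: a (2,1,2) three-finger module reads five key
adenosines across an ~8-nt footprint, the other positions being spacers —
which is why the transcript scanner looks for **A-rich windows**, not only
poly(A) runs.

The package provides:

* `detect_ccch_fingers()`, `extract_features()`,
  `predict_stoichiometry()`, `predict_array_capacity()`,
  `explain_base_specificity()` — the sequence code;
* `read_pdb()`, `find_zn_sites()`, `detect_stacking()`,
  `detect_hbonds()`, `detect_water_bridges()`, `detect_cation_pi()`,
  `classify_base_edge()`, `build_fingerprint()` — the 3D contact grammar;
* `compute_sasa()` (deterministic Shrake–Rupley), `compute_buried_area()`,
  `superpose()` (Kabsch), `domain_rotation_angle()`;
* `array_footprint()`, `scan_windows()`, `find_exact_motif()`,
  `poly_a_runs()` — transcript scanning with 0-based half-open output;
* `rna_mass()`, `protein_mass()`, `complex_mass()` — theoretical average
  masses for light-scattering cross-checks;
* seeded synthetic-fixture generators (`make_finger_sequence()`,
  `make_contact_fixture()`, `make_mini_complex()`, `make_transcript()`)
  so the whole pipeline is testable without external data.

A thin command-line wrapper lives at `inst/cli/polyacode.R`
(`scan-protein`, `scan-rna`, `analyze-structure`, `mass`,
`make-fixtures`).

## Worked example

```r
library(polyAcode)

## sequence code on the finger 3-5 reconstruction (author numbering)
calls <- call_finger_array(nab2_ct_znf35_synthetic())
calls[, c("c1", "c3", "h", "n_adenosines", "rationale")]
#>    c1  c3   h n_adenosines     rationale
#> 1 405 416 420            2 BOTH_AROMATIC
#> 2 426 437 441            1  ONE_AROMATIC
#> 3 446 456 460            2 BOTH_AROMATIC
predict_array_capacity(calls)
#> [1] 5

## theoretical mass of the A8 oligonucleotide (free hydroxyl termini)
rna_mass("AAAAAAAA")
#> <mass_result> ssRNA rna (8 nt): 2571.72 Da (2.6 kDa) [5'-OH/3'-OH]

## a generated three-finger complex, fingerprinted end to end
mc <- make_mini_complex(c(2, 1, 2), seed = 1)
build_fingerprint(mc$model, mc$fingers)
#> <interaction_fingerprint> 5 bound bases; per finger: F1=2, F2=1, F3=2;
#>   buried area 1253.4 A^2; 3 Zn site(s)

## A-rich windows on the 12-nt consensus motif, footprint (2,1,2)
scan_windows("AAAAAAAAAAAG", array_footprint(c(2, 1, 2)))$start
#> [1] 0 1 2 3 4
```

The finger table shows each detected CCCH motif with its author-numbered
cysteine/histidine positions and the code call: fingers with aromatics at
both code positions bind two adenosines, the middle finger with one
aromatic binds one, so the array capacity is five. The fingerprint of the
generated complex recovers exactly the planted per-finger counts, Zn
sites and buried interface. The scanner reports every 8-nt window of the
consensus holding at least five adenosines.

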
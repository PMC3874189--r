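Package: polyAcode
Title: Adenosine Recognition Code and Interaction Fingerprinting for
    CCCH Zinc Finger Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how tandem CCCH zinc finger proteins of
    the Nab2/ZC3H14 family recognise polyadenosine RNA. Detects CCCH
    finger motifs in protein sequences and applies a residue code
    (aromatic side chains two positions after the first and third
    cysteine) to predict how many adenosines each finger binds; classifies
    protein-RNA contacts in crystal structures into a recognition grammar
    (base stacking, adenine N6 to zinc-coordinated cysteine SG hydrogen
    bonds, backbone-amide hydrogen bonds, cation-pi contacts, water
    bridges, Watson-Crick versus Hoogsteen edge orientation); computes
    Shrake-Rupley solvent-accessible and buried surface areas; performs
    Kabsch superposition and domain-rotation analysis; scans transcripts
    for A-rich binding motifs; and computes theoretical average molar
    masses of RNA, protein and complexes. A seeded synthetic-fixture
    generator produces finger sequences of defined code class, idealised
    contact geometries and transcripts with planted motifs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
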
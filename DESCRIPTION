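Package: queftools
Title: Disulfide Stereochemistry and QueF Sequence Census Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analyzing the stereochemistry of protein disulfide
    bridges and for running a conservation census over QueF nitrile
    reductase sequence families. Parses PDB coordinate files, detects
    Cys-Cys bridges, computes the five chi torsion angles spanning a
    disulfide, assigns the 20-class spiral/hook/staple configuration
    taxonomy, and estimates dihedral strain energy from a cosine
    potential. A companion sequence pipeline gates candidate QueF
    sequences on conserved active-site residues and the QueF motif,
    splits the family into unimodular and bimodular subfamilies, and
    tallies conservation of the backdoor cysteine that protects the
    catalytic cysteine as an intramolecular disulfide. Synthetic-data
    generators build cysteine-pair coordinates with prescribed torsions
    and FASTA sets with planted composition so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
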
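Package: bbpkit
Title: Bridged Bicyclic Peptide Scaffolds: Topology, Exact Mass, Structure and Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with bridged bicyclic peptides (BBPs) as drug
    scaffolds. Parses a plain-text dialect of the one-letter BBP sequence
    notation into peptide graphs (residues as nodes, peptide bonds as edges),
    classifies bicyclo[a.b.c] ring topologies and enumerates the bicyclic
    chemical space with exact big-integer sequence counts. Derives elemental
    formulas, monoisotopic masses and ESI adduct m/z values for doubly
    cyclized peptides including side-chain lactam and thioether closures.
    Analyses backbone conformation (phi/psi/omega torsions, cis/trans amides,
    Ramachandran regions for L- and D-residues, beta-turn types, backbone
    hydrogen bonds), scores alpha-helix mimicry by optimal triplet
    superposition, classifies amide-proton NMR temperature coefficients, and
    fits one-set-of-sites ITC isotherms and 1:1 MST dose-response curves.
    Includes seeded synthetic-data generators for torsion-built backbones and
    titration data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
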
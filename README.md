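# bbpkit

Tools for bridged bicyclic peptides (BBPs) — constrained peptide scaffolds
in which two branching "bridgehead" residues (lysine via its ε-amine,
glutamate via its side-chain carboxyl, or a thioether-forming
γ-thia-homoglutamate) are joined by three bridge chains, giving a peptide
graph of cyclomatic number 2. The seven-residue bicyclo[2.2.1] case is the
peptide analog of norbornane. These scaffolds interest peptide chemists and
drug designers because the double cyclization rigidifies the backbone,
resists serum proteolysis, and can present side chains in β-turn- or
α-helix-like arrangements.

The package is aimed at chemists and computational scientists working with
such scaffolds. It provides:

* **Notation and topology** — a plain-text dialect of the one-letter BBP
  notation (`parse_bbp`), graph validation, and `bicyclo[a.b.c]`
  classification (`classify_topology`).
* **Exact mass** — elemental formulas for doubly cyclized peptides
  (lactam, thioether, C-terminal amide, N-methyl chemistry), monoisotopic
  masses and ESI adduct m/z (`formula_of`, `mz_report`), validated against
  a packaged table of printed calc. values.
* **Chemical-space enumeration** — all bicyclic topologies up to a size
  bound and exact big-integer sequence counts, raw or corrected for graph
  automorphisms by Burnside's lemma (`enumerate_topologies`,
  `count_sequences`).
* **Backbone structure** — φ/ψ/ω torsions, cis/trans amides, L/D-aware
  Ramachandran regions, β-turn typing (types I/I′/II/II′/VIII/VIa/VIb),
  and backbone H-bond detection (`backbone_torsions`, `classify_turn`,
  `detect_hbonds`), with PDB I/O.
* **α-helix mimicry** — ideal helix construction and exhaustive residue
  triplet superposition by Kabsch RMSD and Gaussian overlap scoring
  (`build_ideal_helix`, `rank_matches`).
* **NMR and binding** — amide-proton temperature-coefficient H-bond
  classification (`classify_temp_coeff`), the one-set-of-sites ITC
  isotherm with ΔG = ΔH − TΔS = −RT ln K_a thermodynamics (`itc_model`,
  `fit_itc`), and 1:1 quadratic MST fitting (`mst_model`, `fit_mst`).
* **Synthetic data** — seeded torsion-driven backbone building and
  forward-simulated ITC/MST datasets (`build_backbone`, `gen_itc`,
  `gen_mst`), replacing the unpublished raw instrument data.

## Worked example

Parse the norbornapeptide `l1 G k2 f P E1 a2` (lower case = D-residues;
the digit pairs mark the two lactam closures), classify its ring system,
and compute its adduct masses:

```r
library(bbpkit)
g <- parse_bbp("l1 G k2 f P E1 a2")
g
#> <bbp_graph> 7 residues, 8 bonds (cyclomatic 2), C-terminus acid
classify_topology(g)
#> <bbp_topology> bicyclo[2.2.1] (bridged), 7 ring residues
mz_report(g, c("[M+H]+", "[M+Na]+"))
#>    adduct z       mz mz_2dp
#> 1  [M+H]+ 1 725.3981 725.40
#> 2 [M+Na]+ 1 747.3800 747.38
```

The graph has 7 residues and 8 bonds, hence cyclomatic number 2 (a
bicycle); its two bridgeheads carry bridges of 2, 2 and 1 residues — a
norbornane-like bicyclo[2.2.1] system. The neutral formula is C36H52N8O8
(the linear heptapeptide minus two waters of lactamization) and the
protonated and sodiated species land at m/z 725.40 and 747.38.

Fit a simulated calorimetric titration (200 µL cell, 50 µM protein,
15 × 2.5 µL injections of 0.7 mM peptide, 25 °C) with the one-set-of-sites
model:

```r
e <- itc_experiment()
fit <- fit_itc(gen_itc(n = 1, Ka = 1 / 0.80e-6, dH = -5, e), e)
fit
#> <binding fit> n = 1.000, KD = 8e-07 M, dH = -5.000 kcal/mol
#>   dG = -8.288 kcal/mol at 298.15 K
```

The fitter recovers the simulated K_D of 0.80 µM, and the free energy
−8.29 kcal/mol follows from ΔG = −RT ln K_a at 298.15 K.

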
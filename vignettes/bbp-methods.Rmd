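---
title: "Bridged bicyclic peptides: models and methods in bbpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridged bicyclic peptides: models and methods in bbpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbpkit)
```

## The peptide-graph model

A peptide can be read as a mathematical graph: amino acids are nodes and
peptide bonds are edges. Linear and simple cyclic peptides use only
degree-1 and degree-2 nodes; introducing branching residues — diamino acids
such as lysine (via the epsilon-amine) or amino diacids such as glutamate
(via the side-chain carboxyl) — allows polycyclic topologies. A *bridged
bicyclic peptide* (BBP) has two degree-3 bridgehead residues joined by
three bridge paths, giving cyclomatic number 2. The seven-residue case with
bridge sizes (2, 2, 1) is the peptide analog of norbornane
(bicyclo[2.2.1]heptane), hence "norbornapeptide".

`parse_bbp()` reads a plain-text dialect of the one-letter notation: upper
case for L-residues, lower case for D, `Me-` for an N-methylated amide,
trailing digits marking the residue pairs joined by each cyclization, and
special codes `z` (branching gamma-thia-homoglutamate formed by
chloroacetyl-cysteine thioether ligation), `B` (benzoylphenylalanine) and
`K(biot)` (biotinylated lysine). The printed journal typography (bold,
italics, superscripts) carries the same information but is not
machine-readable; this dialect is its lossless, greppable equivalent.
Closure chemistry is inferred from the labelled residues (glutamate with
the chain head: side-chain-to-alpha-amine lactam; lysine with the chain
tail: epsilon-amine-to-C-terminus lactam; glutamate with lysine:
side-chain-to-side-chain lactam; `z` with the chain head: thioether) and
a pair whose chemistry cannot be inferred — two lysines sharing a label,
say — is rejected rather than guessed.

```{r}
g <- parse_bbp("l1 G k2 f P E1 a2")
classify_topology(g)
```

## Exact-mass bookkeeping

`formula_of()` sums chain-residue formulas plus one water, then applies
per-modification deltas: each lactam closes with loss of one water; a
C-terminal carboxamide swaps O for NH; each N-methyl adds CH2; a
chloroacetyl-cysteine thioether closure adds a net C2O (chloroacetylation
followed by HCl loss during ring closure — the two bridge carbons and the
carbonyl oxygen are carried on the bond, and `z` itself contributes a
cysteine residue formula). Monoisotopic element masses are IUPAC values;
adduct m/z uses electron-corrected cation masses (proton 1.007276, Na+
22.989218, K+ 38.963158) and is reported both at full precision and
rounded half-up to two decimals, the convention of printed calc. values.

The packaged `sequences` and `formulas_mz` fixtures transcribe every
printed formula and calc. m/z. A handful of printed formulas contradict
their own printed m/z (the tyrosine series bicycles print the
phenylalanine-series formula; two other entries have obvious copy slips);
these rows carry `formula_consistent = FALSE` and the tests verify them
through their m/z instead. One printed doubly-charged value is internally
inconsistent by one hydrogen with any formula reading and is flagged
`mz_consistent = FALSE`.

## Topology enumeration and the size of the chemical space

`enumerate_topologies()` generates canonical bridge-size triples a >= b >=
c with a + b + c + 2 ring residues. With the defaults (bridged and fused
classes, up to 15 residues) there are 109 topologies: 67 bridged (c >= 1,
one per partition of the interior residue count into exactly three parts —
an identity the tests verify against an independent graph-isomorphism
enumeration) and 42 fused (c = 0). Requiring fused systems to contain no
three-residue ring (`min_bridge = c(fused = 2)`) leaves 97 graphs, which
is the census this family of scaffolds is usually quoted at; because the
defining constraints live in prior work and are not restated alongside the
quoted number, the package exposes them as configuration and reports
counts per configuration rather than hard-coding one reading.

`count_sequences()` measures the sequence space over a 20-letter alphabet,
optionally restricting the two bridgehead positions to a smaller branching
alphabet. Counts use exact base-1e7 big-integer arithmetic (written here,
since no arbitrary-precision integer package is a dependency): the raw
totals exceed 6 x 10^20 at 15 residues and are far beyond exact-double
range. An automorphism-corrected mode applies Burnside's lemma over each
topology's theta-graph symmetry group (bridge permutations within
equal-size classes, optionally composed with the bridgehead swap), so that
relabellings related by a graph symmetry count once; the commonly quoted
3.1 x 10^19 members is not reproduced by any configuration tested here and
the package simply reports its own totals side by side. Counting of
directed C-to-N orientation classes per bridge is not implemented.

## Backbone geometry

Torsions follow the IUPAC sign convention in (-180, 180]. A peptide bond
is cis when |omega| < 90 degrees. Ramachandran assessment uses coarse
convex polygon approximations of the standard generic preferred/allowed
contours (documented constants in the source; a published contour set can
be substituted), mirrored through (phi, psi) -> (-phi, -psi) for
D-residues.

Beta-turn typing compares the central (phi, psi) pairs of a four-residue
window against the canonical Hutchinson–Thornton values for types I, I',
II, II', VIII, VIa and VIb, with the community tolerance of 30 degrees
(one angle allowed 45); type VI additionally requires a cis peptide bond
between the two central residues, and unmatched windows are type IV. The
crystallographic turn census of the original structures is *not* a desk
computation — it needs the deposited coordinates — so the suite exercises
the classifier on constructed geometry: canonical angles are an identity,
moderate perturbation preserves the type, and mirroring a structure maps
every type to its prime counterpart.

Hydrogen bonds are detected between reconstructed amide protons (placed in
the C(i-1)–N(i)–CA(i) plane at 1.01 A, bisecting the exterior angle;
prolines and N-methylated amides have none) and carbonyl oxygens, with
N...O <= 3.5 A and N-H...O >= 120 degrees, excluding the two trivial
adjacent contacts. On an ideal helix this recovers the full i+4 -> i
ladder.

## Helix mimicry

`build_ideal_helix()` constructs a poly-alanine helix at the textbook
torsions (-57, -47) — the source structures come with no stated values, so
the textbook pair is used — with CB atoms placed tetrahedrally (improper
dihedral C–N–CA–CB of +122.5 degrees for L-residues, negated for D). A
seven-residue helix — one double turn — has 35 residue triplets;
`rank_matches()` superposes every query triplet onto every helix triplet
(1225 pairs for 7 vs 7) in CA, CB or combined atom mode, with residues
corresponded in sequence order (a reversed correspondence is available but
off by default, as no convention is stated). Superposition is closed-form
Kabsch via SVD restricted to proper rotations, so a chiral motif cannot
match its mirror image; the tests check it against a brute-force
rotation-grid oracle. Alongside RMSD (the default ranking key) a Gaussian
atom-pair overlap score sum exp(-d^2/2 sigma^2)/n with sigma = 1 A is
reported, keeping the spirit of atom-pair fitting functions used for
small-molecule shape comparison without depending on one implementation.

## NMR temperature coefficients

Amide-proton chemical-shift temperature coefficients (-d delta/dT, ppb/K)
classify hydrogen bonding: below 4.0 fully bonded, 4.0–7.0 inclusive
partially bonded, above 7.0 unbonded. The boundary 4.0 goes to "partial"
because the printed thresholds write "< 4.0" for full and "= 4.0–7.0" for
partial. The packaged table of 63 coefficients (61 determined, 2 not
determined) reproduces the printed boldface partition exactly: boldface
if and only if the classifier says "full".

## Binding models

**ITC.** The one-set-of-sites isotherm computes bound fraction from the
single-site quadratic at instrument-style effective concentrations: after
cumulative injection volume dV into cell volume V0, the cell species is
scaled by (1 - dV/2V0)/(1 + dV/2V0) and the titrant by (dV/V0)/(1 +
dV/2V0), and per-injection heats are differences of cumulative heats plus
a displaced-volume term — the convention of the standard instrument
software, switchable to naive dilution (conventions can differ in the
third decimal; both are implemented). Defaults follow the published
protocol: 200 uL cell, 50 uM protein, fifteen 2.5 uL injections of 0.7 mM
peptide at 25 C. `fit_itc()` estimates (n, Ka, dH) by Levenberg–Marquardt
least squares with Ka on a log scale, warns when the Wiseman c-value
leaves the informative 1–1000 window, and completes the thermodynamics
through dG = -RT ln Ka = dH - T dS with R = 1.98 cal/(mol K), so the
Gibbs identity holds to machine precision on every fit. A drop-first-
injection flag is deliberately absent: the protocol modelled does not
discard one.

**MST.** Fraction bound follows the exact 1:1 quadratic solution; the
signal is a linear interpolation between free and bound plateaus
(thermophoresis physics is not modelled). The default design is the
published one: 10 nM labeled protein and a 2-fold, 15-level ligand series
from 500 uM, mixed 1:1 (final 250 uM down to 15.3 nM). The assay
description mentions sixteen 1:1 dilutions, but the printed endpoints
imply 15 levels at factor 2, so the generator takes the level count
explicitly and the fixture stores 15. `fit_mst()` fits (KD, plateaus) and
flags fits whose transition lies outside the measured range or whose
series shows none.

The published affinities (ITC KD 0.80 uM, MST KD 4.5 uM for the
calmodulin-binding bicycle) are carried in the design fixtures as ground
truths for self-recovery: the raw instrument data are not published, so
the quantitative check is that each fitter recovers the ground truth from
its own forward model — exactly on noiseless data, and within 10 percent
(ITC, 2 percent noise) / 15 percent (MST, 5 percent noise) median error
over seeded Monte-Carlo replicates.

## Synthetic backbones

`build_backbone()` places N, CA, C, O and CB sequentially (natural
extension reference frames) with standard geometry: bonds N-CA 1.458,
CA-C 1.525, C-N 1.329, C=O 1.231, CA-CB 1.530 A; angles N-CA-C 111.2,
CA-C-N 117.2, C-N-CA 121.7 degrees. Torsions round-trip through
`backbone_torsions()` to 1e-6 degrees, which is the package's stand-in for
refined experimental coordinates: it emulates backbone geometry at
specified torsions plus optional Gaussian coordinate noise, and does not
emulate side chains beyond CB, solvent, crystal packing, or the restrained
molecular-dynamics refinement behind the deposited structures — so
structure-suite tests demonstrate correctness of the geometry operators,
not reproduction of any particular crystal or NMR structure. All
generators are pure functions of (parameters, seed).

## Numerical choices and problem sizes

Rounding of m/z for table comparison is half-up at two decimals. The
turn classifier breaks ties by the smallest summed circular deviation.
Degenerate (collinear) point sets in superposition are flagged;
superposition of fewer than three points is refused. Monte-Carlo recovery
studies in the tests use 60–100 seeded replicates of 15-point titrations,
and graph-isomorphism cross-checks run to ring size 10 and census size 20
— sizes chosen so the whole suite completes in well under a minute while
still exercising every code path.

## Known limitations

* The bicyclo descriptor covers graphs with exactly two degree-3 ring
  nodes; spiro systems and higher polycycles are reported as unsupported.
* Ramachandran polygons are coarse convex approximations; classifications
  near region boundaries should not be over-interpreted.
* The MST model omits thermophoretic physics; plateau values are fit
  parameters, not predictions.
* Turn windows follow the written chain only; windows across closure
  bonds are not enumerated by default.
* The "new type of structural arrangement" loop geometry and the
  bridge-up/bridge-down distinction observed in the original structures
  have no printed torsions and no geometric definition respectively, so
  no classifier is offered for them; with deposited coordinates supplied
  as PDB, `find_turns()` and `rank_matches()` run as optional checks.
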
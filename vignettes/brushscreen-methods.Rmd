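---
title: "Methods: descriptor screening and similarity clustering of polymer-brush monomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor screening and similarity clustering of polymer-brush monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushscreen)
```

`brushscreen` screens a panel of small hydrophilic monomers — the repeating
units of polymer brushes grafted onto nanoparticle surfaces — along two
complementary axes: a *physicochemical* axis (descriptor vectors, rule
filters, ADME classification, descriptor-space clustering) and a
*structural* axis (exact maximum-common-substructure similarity). The two
views deliberately disagree for some pairs: two molecules can share most of
their scaffold yet sit far apart in descriptor space, and vice versa. This
vignette documents the models, the pinned conventions, and the numerical
choices, in the order the pipeline applies them.

## 1. Molecular graphs and the valence model

All computation is 2D: a molecule is a labelled graph of heavy atoms with
implicit hydrogens, parsed from SMILES. The supported dialect is the organic
subset (C, N, O, S, P, halogens; aromatic lowercase forms), bracket atoms
with explicit hydrogen counts and formal charges, branches, ring closures,
and single/double/triple/aromatic bonds. Stereochemistry, isotopes and
multi-fragment inputs are rejected: every descriptor used downstream is
constitution-only, so stereo support would add parsing surface without
changing a single number, and the packaged panel needs none of it.

Implicit hydrogens come from a fixed valence table — C 4; N 3; O 2; S 2/4/6;
P 3/5; halogens 1 — with charge adjustments that matter for zwitterions:
a positive charge on N/O/S/P adds one bonding slot (quaternary N⁺ is
tetravalent with no H), a negative charge removes one (sulfonate and
phosphate O⁻ are monovalent), and hexavalent sulfur makes sulfonate sulfur
hydrogen-free. The smallest allowed valence accommodating the explicit
bond-order sum is filled with hydrogens; an unsatisfiable atom is a parse
error, never a silent repair.

Aromatic rings are kekulized on input (alternating orders found by
backtracking; lone-pair donors such as aromatic O/S and pyrrole-type N
receive no ring double bond), and aromatic flags are retained alongside the
kekulized orders. This gives one uniform valence model instead of a separate
aromatic bookkeeping path; the panel contains a single aromatic system (the
pyridinium monomer), so full Hückel perception would be over-engineering.
Ring perception keeps a smallest-set-of-smallest-rings basis built from
per-bond shortest cycles with GF(2) independence.

## 2. The descriptor vector

Ten descriptors per molecule: molecular weight (g/mol, IUPAC 2021 atomic
weights), heavy-atom count, fraction Csp³, H-bond acceptors and donors,
rotatable bonds, TPSA (Å²), WLOGP, molar refractivity, and ESOL log S.
Definitions the literature leaves loose are pinned as follows:

* **HBA**: N and O atoms, excluding amide and pyrrole-type nitrogens and
  positively charged nitrogens. **HBD**: N/O atoms with at least one
  hydrogen, counted once per atom regardless of hydrogen count.
* **Rotatable bonds**: acyclic single bonds between two non-terminal heavy
  atoms, excluding amide C–N.
* **TPSA**: Ertl group contributions keyed on (element, aromaticity, charge,
  hydrogen count, bond-order pattern, 3-ring membership), including the
  sulfur/phosphorus extension — without it the sulfobetaine and
  phosphorylcholine monomers would be uncomputable. An environment missing
  from the table is an error naming the environment, not a zero.
* **WLOGP / MR**: the Wildman–Crippen atom-additive model, reimplemented as
  ordered typing rules over the atom neighbourhood with the published
  contribution table packaged as data. Hydrogens contribute through their
  own types (hydrocarbon, alcohol, N–H, acid). This single table-driven logP
  stands in for multi-predictor consensus scales: it is fully reproducible
  offline, and every other prediction in the package (Egan, Ghose, the egg)
  is interpreted on the same WLOGP scale.
* **ESOL**: the Delaney linear model
  `log S = 0.16 − 0.63·WLOGP − 0.0062·MW + 0.066·RB − 0.74·AP`, with AP the
  aromatic fraction of heavy atoms and RB the rotatable-bond *count* (the
  published model's regressor).

The typing logic was validated during development against an independent
implementation of the same published models (rdkit) on the full panel plus a
probe set covering every atom type the panel exercises; the frozen reference
values live in the test suite.

All rule thresholds (Lipinski/Ghose/Veber/Egan/Muegge/lead-likeness), ESOL
coefficients, egg geometry and bioavailability score classes live in one
versioned JSON constants file (`inst/extdata/constants.json`) rather than in
code, so an audit reads one file.

## 3. BOILED-Egg classification

Gastrointestinal absorption and BBB permeation are ellipse-membership tests
in the (TPSA, WLOGP) plane: white ellipse (centre 71.05 Å², 2.29; semi-axes
71.04 Å², 4.37; tilt −1.03°) for high GI absorption, yolk (centre 38.12 Å²,
3.48; semi-axes 41.03 Å², 5.56; tilt −0.15°) for BBB permeation. The two
memberships are evaluated independently — the yolk is not assumed to be a
subset of the white. The published parameter tuples circulate with an
ambiguous axis convention; the packaged semi-axis reading was fixed once by
checking classifier behaviour on well-known external reference drugs
(caffeine BBB-permeant at WLOGP −1.03; atenolol non-permeant; sulfasalazine
low-absorption), not by fitting to the panel. Zwitterionic inputs are
classified by the same geometry but flagged with a warning, since the egg
was calibrated on neutral species — for strongly charged monomers the calls
should be read as "position in the plane", not as a validated permeability
prediction.

## 4. MCS similarity and its calibration

For each molecule pair the package finds the *exact* maximum common
connected substructure by backtracking: mappings grow only through bonds
present (and compatible) in both molecules, explored pairs are forbidden in
later sibling branches so each maximal common subgraph is enumerated once,
and a size bound prunes the rest. Exactness (rather than a heuristic with a
timeout) is what makes every similarity value, and every test, bit-stable;
a hard guard of 40 heavy atoms per molecule keeps the search in the regime
where exactness is affordable (the full 14×14 panel matrix takes well under
a second).

The Tanimoto coefficient is `c/(a+b+c)`. Three conventions are deliberately
exposed as `match_semantics` rather than hard-coded, because published
coefficients rarely state them: the feature unit (heavy atoms, or heavy
atoms plus bonds), charge sensitivity of the atom match, and bond-order
matching (exact vs any). `calibrate_semantics()` grid-searches the eight
variants against a set of published reference coefficients and returns the
variant minimizing the maximum absolute deviation, with ties resolved in a
documented preference order (atom unit, charge-blind, any-order first) and
the residuals attached for logging. On the packaged panel the calibration
selects the atom feature unit, charge-blind, exact bond order.

Two structural facts about this statistic are worth stating because no
calibration can move them. First, `c` can never exceed the smaller
molecule's atom count, so the coefficient has a hard ceiling of
`min(|A|,|B|) / max(|A|,|B|)` per pair — for a 5-atom molecule inside a
7-atom molecule the ceiling is 5/7 ≈ 0.714, for an 8-atom molecule against
a 15-atom one it is 8/15 ≈ 0.533, regardless of semantics. Second,
counting bonds as features lowers coefficients further for sparse common
subgraphs. Published coefficients above these ceilings cannot be reproduced
by any exact-MCS convention and most likely reflect a different (or
hydrogen-inclusive) feature definition in the original web tooling; the
calibration residuals make such discrepancies visible instead of hiding
them.

## 5. Clustering

The descriptor table is z-scored per column (population standard deviation;
constant columns are dropped with a warning) before Euclidean distances.
Scaling is a genuine design choice the study description leaves open: on raw
scales molecular weight (range ~70–310) dominates count-valued descriptors
(0–10) and the dendrogram degenerates into a molecular-weight ordering, so
standardization is the default and the raw variant remains available
(`standardize = FALSE`); both variants are exercised by the acceptance
checks.

Agglomeration is group-average (UPGMA): the distance between clusters is the
unweighted mean of cross-cluster leaf distances and the merge height is that
distance. Ties break to the smallest (row, column) pair in cluster-creation
order, making trees bit-reproducible under row permutations (verified by
property test). Heights are checked non-decreasing; the implementation is
cross-checked against `stats::hclust(method = "average")` — heights and
cophenetic matrices must agree exactly — rather than trusted on faith.
Clade membership and sibling queries work on the merge list; the clustroid
of a member set minimizes the within-set distance sum with lexicographic
tie-break. Newick export writes branch lengths as parent height minus child
height (leaves at height zero) with children ordered by smallest leaf
label; `ape::read.tree` accepts the output (test-suite smoke check).

Internal clades are referred to by merge order, never by the drawing-order
numbers a plotting program would assign: only co-membership statements are
meaningful across implementations.

## 6. The synthetic-molecule generator

Property-based tests need molecules that nobody hand-picked. The generator
builds random connected graphs honouring the valence model: heavy-atom
counts uniform on a range (default 3–12, matching the panel's 5–21 scale at
test-friendly sizes), element draws weighted C 0.62 / N 0.12 / O 0.20 /
S 0.04 / P 0.02 (roughly the panel's composition), occasional double bonds,
one optional ring closure (default probability 0.25 — the panel is mostly
acyclic with single rings), and with probability `charge_pair_probability`
(default 0.2) a balanced N⁺/O⁻ pair emulating the zwitterions. Every
generated molecule is emitted as SMILES, reparsed, and kept only if the
round-trip is graph-isomorphic — the generator is therefore also a
continuous test of the parser/writer pair. Seeded runs are bit-reproducible.

What the generator does *not* emulate: aromatic systems, fused rings,
realistic functional-group frequencies, tautomers. Tests passing on
generated molecules therefore certify the algorithms (valence handling,
MCS exactness, clustering correctness), not chemical realism; the packaged
panel covers the chemistry the generator cannot.

## 7. Test problem sizes and oracles

The suite runs three independent-oracle comparisons at sizes chosen to keep
the exhaustive oracles exact: MCS backtracking against a subset-enumeration
oracle on 200 seeded random pairs of 4–8-atom molecules (the oracle
enumerates atom subsets and injections, a completely different search
strategy); UPGMA against `stats::hclust` on 100 random distance matrices
with up to 8 leaves; and parser round-trip on 1,000 seeded molecules of
2–14 atoms. The full suite completes in well under a minute on one CPU.

## 8. Known limitations

* Descriptor definitions approximate the web-tool originals where those are
  proprietary or under-specified (HBA/HBD exclusions, single-model WLOGP
  instead of consensus logP); absolute rule-filter outcomes can differ from
  web services even when every packaged number is correct.
* The BOILED-Egg geometry is applied outside its calibration domain for
  zwitterions (flagged per molecule).
* MCS-based Tanimoto values are convention-bound; compare coefficients only
  within one semantics, and expect hard ceilings for size-mismatched pairs
  (§4).
* The monomer panel represents isolated repeating units; descriptor values
  for a monomer do not transfer quantitatively to a grafted polymer brush,
  where chain conformation and inter-chain interactions dominate.
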
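# brushscreen

Hydrophilic polymer brushes (PEG and its candidate replacements) are grafted
onto nanoparticle surfaces to resist opsonization and penetrate mucus. Picking
the right monomer — the repeating unit of such a brush — from a panel of
candidates is usually done by wet-lab trial and error. `brushscreen`
implements a desk-screening pipeline for such panels: it computes
physicochemical descriptors and ADME predictions for each candidate, measures
pairwise structural similarity, and clusters the panel, so that structurally
or physicochemically redundant candidates are recognized before any synthesis
is planned. The package ships the 14-monomer panel of hydrophilic
brush-forming monomers (oxazoline, acrylamide, vinylpyrrolidone, glycerol,
acryloyl morpholine, dimethyl acrylamide, HPMA, HEMA, sialic acid, and the
zwitterionic carboxybetaine/sulfobetaine/phosphorylcholine/pyridinio-sulfonate
monomers) as its canonical fixture.

It is aimed at nanomedicine and polymer-chemistry groups who want a
reproducible, scriptable equivalent of the usual web-tool workflow
(SwissADME-style descriptors, MCS similarity, dendrogram) that runs offline
and is fully testable.

## What it computes

* **Molecular graphs from SMILES** — organic subset plus bracket atoms with
  formal charges (the zwitterions are the hard cases), ring perception,
  kekulization, and a pinned valence model for implicit hydrogens.
* **Descriptors** — molecular weight, heavy atoms, fraction Csp³, H-bond
  acceptors/donors, rotatable bonds, Ertl TPSA (with the S/P extension),
  Wildman–Crippen logP (WLOGP) and molar refractivity, and the Delaney ESOL
  log S: `log S = 0.16 − 0.63·logP − 0.0062·MW + 0.066·RB − 0.74·AP`.
* **Rule filters** — Lipinski (≤ 1 violation passes), Ghose, Veber, Egan,
  Muegge, lead-likeness, plus the Abbott bioavailability score.
* **BOILED-Egg ADME classification** — gastrointestinal absorption (white
  ellipse) and blood–brain-barrier permeation (yolk ellipse) from the
  position of each molecule in the (TPSA, WLOGP) plane.
* **MCS Tanimoto similarity** — exact maximum common connected substructure
  for every molecule pair and the coefficient `T = c/(a+b+c)`, where `c`
  counts shared features and `a`, `b` the features unique to each molecule.
  The match semantics (feature unit, charge sensitivity, bond-order
  matching) can be calibrated against published reference coefficients.
* **Hierarchical clustering** — z-scored descriptors, Euclidean distances,
  group-average (UPGMA) linkage with deterministic tie-breaks, clade and
  clustroid queries, Newick export, and heatmap leaf ordering.

## Worked example

```r
library(brushscreen)

panel <- load_panel()          # the packaged 14-monomer panel
panel$AA
#> <molecule> AA: 5 heavy atoms, 4 bonds, formula C3H5NO, net charge +0

round(unlist(descriptor_vector(panel$AA)[-1]), 3)
#> molecular_weight  heavy_atoms  fraction_csp3    hba    hbd
#>           71.079        5.000          0.000  1.000  1.000
#> rotatable_bonds     tpsa   wlogp  molar_refractivity  esol_logs
#>           1.000   43.090  -0.342              19.391      0.001
```

Acrylamide is a 71 g/mol, fully sp²-backboned amide: one acceptor (the
carbonyl oxygen), one donor (the NH₂ nitrogen), TPSA 43.1 Å², and a mildly
hydrophilic WLOGP of −0.34. Its (TPSA, WLOGP) point falls inside both egg
ellipses:

```r
boiled_egg(43.09, -0.342)
#>    tpsa   wlogp gi_absorption bbb_permeant
#> 1 43.09 -0.3423          high          yes
```

Structural similarity of the two hydroxyalkyl methacrylamides:

```r
mcs(panel$HPMA, panel$HEMA)
#> <mcs_result> HPMA vs HEMA: c=9 a=1 b=0 tanimoto=0.900
```

All nine HEMA heavy atoms map into HPMA, which has one extra methyl, giving
`9/(9+1) = 0.90` — these two monomers are near-duplicates of each other on
the similarity surface.

The whole pipeline (descriptors, rules, egg screen, similarity matrix,
dendrogram, manifest) runs in one call:

```r
run_pipeline(pipeline_config(output_dir = "results"))
```

or from the shell via the thin wrapper `inst/scripts/screen.R`. In the
resulting dendrogram of standardized descriptors, the top split isolates
sialic acid (the only pyranose-ring monomer, and the panel's TPSA and size
outlier) from the remaining 13 monomers, which split 8 (neutral
carbon-backbone monomers) versus 5 (zwitterions), with HPMA/HEMA and
SBMA/MPC as sibling pairs.

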
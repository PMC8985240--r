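Package: brushscreen
Title: Descriptor-Based Screening and Similarity Clustering of Polymer-Brush Monomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screening pipeline for the low molecular weight
    monomers used to graft hydrophilic polymer brushes onto nanoparticle
    surfaces. Parses SMILES into molecular graphs, computes SwissADME-style
    physicochemical descriptors (molecular weight, fraction Csp3, hydrogen-bond
    counts, rotatable bonds, Ertl topological polar surface area,
    Wildman-Crippen logP and molar refractivity, ESOL aqueous solubility),
    evaluates rule-based drug-likeness filters (Lipinski, Ghose, Veber, Egan,
    Muegge, lead-likeness) and the BOILED-Egg gastrointestinal-absorption /
    blood-brain-barrier classifier, measures pairwise structural similarity by
    an exact maximum-common-substructure Tanimoto coefficient, and clusters the
    panel by group-average (UPGMA) agglomerative clustering of standardized
    descriptors with Newick export. Ships the 14-monomer polymer-brush panel as
    a fixture together with a seeded generator of random small organic
    molecules (including zwitterions) for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
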
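# 14-monomer polymer-brush panel (repeating units of hydrophilic graft
# polymers studied as PEG alternatives for nanoparticle surface
# functionalization).
#
# PROVENANCE: the structures are RECONSTRUCTED from the monomer names using
# the standard structures of the polymer-brush / zwitterionic-polymer
# literature; the original tabulated SMILES were published as an image and are
# not machine-readable. Notes per entry:
#   OZ    2-oxazoline (4,5-dihydro-1,3-oxazole), repeating unit of POZ
#   AA    acrylamide
#   VP    1-vinyl-2-pyrrolidone
#   Gly   glycerol (polyglycerol repeating unit)
#   AcM   4-acryloylmorpholine
#   DMA   N,N-dimethylacrylamide
#   HPMA  N-(2-hydroxypropyl)methacrylamide
#   HEMA  N-(2-hydroxyethyl)methacrylamide -- transcribed as the
#         methacrylAMIDE per the source text's name expansion, although HEMA
#         conventionally abbreviates hydroxyethyl methacrylate
#   SA    sialic acid (N-acetylneuraminic acid), polysialic acid unit
#   CBAA  carboxybetaine acrylamide:
#         2-[(3-acrylamidopropyl)dimethylammonio]acetate (carboxymethyl arm;
#         one- and two-carbon arm variants both occur in the literature)
#   CBMA  carboxybetaine methacrylate:
#         3-[[2-(methacryloyloxy)ethyl]dimethylammonio]propanoate
#   SBMA  sulfobetaine methacrylate:
#         3-[[2-(methacryloyloxy)ethyl]dimethylammonio]propane-1-sulfonate
#   MPC   2-(methacryloyloxy)ethyl phosphorylcholine
#   VPPS  3-(4-vinylpyridinium-1-yl)propane-1-sulfonate
C1CN=CO1	OZ
C=CC(N)=O	AA
C=CN1CCCC1=O	VP
OCC(O)CO	Gly
C=CC(=O)N1CCOCC1	AcM
C=CC(=O)N(C)C	DMA
C=C(C)C(=O)NCC(C)O	HPMA
C=C(C)C(=O)NCCO	HEMA
CC(=O)NC1C(O)CC(O)(C(=O)O)OC1C(O)C(O)CO	SA
C=CC(=O)NCCC[N+](C)(C)CC(=O)[O-]	CBAA
C=C(C)C(=O)OCC[N+](C)(C)CCC(=O)[O-]	CBMA
C=C(C)C(=O)OCC[N+](C)(C)CCCS(=O)(=O)[O-]	SBMA
C=C(C)C(=O)OCCOP(=O)([O-])OCC[N+](C)(C)C	MPC
C=Cc1cc[n+](CCCS(=O)(=O)[O-])cc1	VPPS
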
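test_that("parse_smiles builds the expected graphs for simple molecules", {
  w <- parse_smiles("O", "water")
  expect_equal(n_atoms(w), 1L)
  expect_equal(w$atoms$implicit_h, 2L)
  expect_equal(net_charge(w), 0L)

  aa <- parse_smiles("C=CC(N)=O", "AA")
  expect_equal(n_atoms(aa), 5L)
  expect_equal(sum(aa$atoms$implicit_h), 5L)
  expect_equal(molecular_formula(aa), "C3H5NO")
  # bond multiset {C=C, C-C, C-N, C=O}
  bond_kinds <- sort(apply(aa$bonds, 1L, function(b) {
    paste(sort(aa$atoms$element[c(b[["a1"]], b[["a2"]])]), collapse = "") |>
      paste0(":", b[["order"]])
  }))
  expect_equal(bond_kinds, sort(c("CC:2", "CC:1", "CN:1", "CO:2")))
})

test_that("malformed SMILES raise parse errors naming the offending position", {
  expect_error(parse_smiles("C(", "bad"), "position 2")
  expect_error(parse_smiles("CC1CC", "bad"), "unmatched ring-closure")
  expect_error(parse_smiles("Cq", "bad"), "position 2")
  expect_error(parse_smiles("[Xx]C", "bad"), "unknown element")
  expect_error(parse_smiles("O(C)(C)(C)C", "bad"), "valence overflow")
  expect_error(parse_smiles("C.C", "bad"), "disconnected")
  expect_error(parse_smiles("C/C=C/C", "bad"), "stereochemistry")
  expect_error(parse_smiles("", "bad"), "non-empty")
})

test_that("ring perception finds the smallest set of smallest rings", {
  expect_length(ring_perception(parse_smiles("OCC(O)CO", "glycerol")), 0L)

  benz <- parse_smiles("c1ccccc1", "benzene")
  expect_length(benz$rings, 1L)
  expect_length(benz$rings[[1L]], 6L)

  # fused bicyclic: decalin has exactly two 6-rings
  dec <- parse_smiles("C1CCC2CCCCC2C1", "decalin")
  expect_length(dec$rings, 2L)
  expect_equal(lengths(dec$rings), c(6L, 6L))

  sa <- panel_fixture()$SA
  expect_length(sa$rings, 1L)
  ring_elems <- sa$atoms$element[sa$rings[[1L]]]
  expect_length(ring_elems, 6L)
  expect_equal(sum(ring_elems == "O"), 1L)  # pyranose ring
})

test_that("the valence model assigns implicit hydrogens and rejects overflow", {
  expect_equal(implicit_hydrogen_count("O", 1L), 1L)
  expect_equal(implicit_hydrogen_count("N", 4L, charge = 1L), 0L)
  expect_equal(implicit_hydrogen_count("C", 2L), 2L)
  expect_equal(implicit_hydrogen_count("S", 3L), 1L)  # next allowed valence 4
  expect_error(implicit_hydrogen_count("C", 5L), "valence overflow")

  # sulfonate sulfur is hexavalent with no hydrogens
  sb <- parse_smiles("CS(=O)(=O)[O-]", "mesylate")
  s_idx <- which(sb$atoms$element == "S")
  expect_equal(sb$atoms$implicit_h[s_idx], 0L)
  expect_equal(net_charge(sb), -1L)
})

test_that("alternative spellings of the same molecule are isomorphic with equal descriptors", {
  g1 <- parse_smiles("OCC(O)CO", "gly1")
  g2 <- parse_smiles("C(CO)(O)CO", "gly2")
  expect_true(molecules_isomorphic(g1, g2))
  d1 <- descriptor_vector(g1); d2 <- descriptor_vector(g2)
  num <- vapply(d1, is.numeric, logical(1L))
  expect_equal(unlist(d1[num]), unlist(d2[num]))

  v1 <- parse_smiles("C=C(C)C(=O)NCC(C)O", "hpma1")
  v2 <- parse_smiles("OC(C)CNC(=O)C(C)=C", "hpma2")
  expect_true(molecules_isomorphic(v1, v2))
  expect_equal(wlogp(v1), wlogp(v2))
  expect_equal(tpsa(v1), tpsa(v2))
})

test_that("aromatic rings kekulize to alternating orders with correct hydrogen counts", {
  b <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(sort(b$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(all(b$atoms$implicit_h == 1L))
  expect_true(all(b$atoms$aromatic))

  py <- parse_smiles("c1cc[nH]c1", "pyrrole")
  n_idx <- which(py$atoms$element == "N")
  expect_equal(py$atoms$implicit_h[n_idx], 1L)
  expect_equal(sum(py$bonds$order == 2L), 2L)

  vpps <- panel_fixture()$VPPS
  np <- which(vpps$atoms$element == "N")
  expect_equal(vpps$atoms$charge[np], 1L)
  expect_equal(vpps$atoms$implicit_h[np], 0L)
  expect_error(parse_smiles("cc", "bad"), "not in any ring")
})

test_that("molecule JSON dump round-trips the graph", {
  m <- panel_fixture()$SBMA
  js <- jsonlite::fromJSON(molecule_to_json(m))
  expect_equal(js$formula, molecular_formula(m))
  expect_equal(nrow(js$atoms), n_atoms(m))
  expect_equal(nrow(js$bonds), n_bonds(m))
})

test_that("smi files read and write with comments and identifiers", {
  tmp <- tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO ethanol", "", "C=CC(N)=O\tAA"), tmp)
  mols <- read_smi(tmp)
  expect_length(mols, 2L)
  expect_equal(mols[[1L]]$id, "ethanol")
  expect_equal(mols[[2L]]$id, "AA")
  tmp2 <- tempfile(fileext = ".smi")
  write_smi(mols, tmp2)
  again <- read_smi(tmp2)
  expect_true(molecules_isomorphic(mols[[2L]], again[[2L]]))
})
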
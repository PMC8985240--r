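test_that("the packaged panel loads with verified checksum and parses fully", {
  panel <- load_panel()
  expect_length(panel, 14L)
  expect_equal(names(panel),
               c("OZ", "AA", "VP", "Gly", "AcM", "DMA", "HPMA", "HEMA", "SA",
                 "CBAA", "CBMA", "SBMA", "MPC", "VPPS"))
  expect_false(anyDuplicated(names(panel)) > 0L)

  expect_equal(molecular_formula(panel$Gly), "C3H8O3")
  expect_length(panel$SA$rings, 1L)

  # all zwitterionic monomers balance to net charge zero
  expect_true(all(vapply(panel, net_charge, integer(1L)) == 0L))
  expect_setequal(names(panel)[vapply(panel, is_zwitterion, logical(1L))],
                  c("CBAA", "CBMA", "SBMA", "MPC", "VPPS"))
})

test_that("panel descriptor table is stable across recomputation", {
  panel <- load_panel()
  t1 <- descriptor_table(panel)
  t2 <- descriptor_table(panel)
  expect_identical(t1, t2)
})

test_that("generation is reproducible from the seed", {
  s <- synthetic_spec(seed = 7L, n_molecules = 25L, heavy_atom_range = c(3L, 10L))
  m1 <- generate_molecules(s)
  m2 <- generate_molecules(s)
  expect_identical(vapply(m1, function(m) m$smiles, ""),
                   vapply(m2, function(m) m$smiles, ""))
})

test_that("generated molecules satisfy the valence model and round-trip", {
  mols <- generate_molecules(synthetic_spec(seed = 11L, n_molecules = 120L,
                                            heavy_atom_range = c(2L, 12L)))
  for (m in mols) {
    expect_true(n_atoms(m) >= 2L && n_atoms(m) <= 12L)
    reparsed <- parse_smiles(m$smiles, m$id)
    expect_true(molecules_isomorphic(m, reparsed))
    bos <- bond_order_sums(m)
    for (a in seq_len(n_atoms(m))) {
      av <- allowed_valences(m$atoms$element[a], m$atoms$charge[a])
      expect_true((bos[a] + m$atoms$implicit_h[a]) %in% av)
    }
  }
})

test_that("charge_pair_probability = 1 yields balanced zwitterions", {
  mols <- generate_molecules(synthetic_spec(seed = 13L, n_molecules = 40L,
                                            heavy_atom_range = c(4L, 9L),
                                            charge_pair_probability = 1))
  for (m in mols) {
    expect_equal(net_charge(m), 0L)
    expect_true(any(m$atoms$charge > 0L))
    expect_true(any(m$atoms$charge < 0L))
  }
})

test_that("infeasible generator specs error out", {
  expect_error(synthetic_spec(heavy_atom_range = c(0L, 0L)), "min >= 1")
  expect_error(synthetic_spec(ring_probability = 2), "probabilities")
  expect_error(
    generate_molecules(synthetic_spec(seed = 1L, n_molecules = 3L,
                                      heavy_atom_range = c(1L, 1L),
                                      charge_pair_probability = 1)),
    "failed to satisfy"
  )
})

test_that("perturbations are single edits with the documented properties", {
  propane <- parse_smiles("CCC", "propane")
  ethane_like <- perturb(propane, "delete_terminal_atom")
  expect_true(molecules_isomorphic(ethane_like, parse_smiles("CC", "ethane")))

  mut <- perturb(parse_smiles("CCC", "propane"), "mutate_element", target = 1L,
                 new_element = "N")
  expect_equal(sort(mut$atoms$element), c("C", "C", "N"))
  expect_equal(n_bonds(mut), 2L)

  expect_error(perturb(parse_smiles("C", "methane"), "delete_terminal_atom"),
               "single-atom")
  expect_error(perturb(parse_smiles("COC", "ether"), "mutate_element",
                       target = 2L, new_element = "F"),
               "cannot accommodate")

  parent <- parse_smiles("CCOCC", "parent")
  child <- perturb(parent, "delete_terminal_atom")
  r <- mcs(parent, child)
  expect_gt(r$tanimoto, 0)
  expect_lt(r$tanimoto, 1)
})
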
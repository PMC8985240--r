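mol <- function(smi, id = "m") parse_smiles(smi, id)

test_that("mcs handles the elementary cases exactly", {
  gly <- mol("OCC(O)CO", "gly")
  self <- mcs(gly, gly)
  expect_equal(self$c, n_atoms(gly))
  expect_equal(self$a, 0L)
  expect_equal(self$b, 0L)
  expect_equal(self$tanimoto, 1)

  none <- mcs(mol("C", "methane"), mol("O", "water"))
  expect_equal(none$c, 0L)
  expect_equal(none$tanimoto, 0)

  ep <- mcs(mol("CC", "ethane"), mol("CCC", "propane"))
  expect_equal(ep$c, 2L)
  expect_equal(ep$a, 0L)
  expect_equal(ep$b, 1L)
  expect_equal(ep$tanimoto, 2 / 3)
})

test_that("the mapping is a deterministic lexicographic minimum", {
  a <- mol("CCO", "a"); b <- mol("OCC", "b")
  r1 <- mcs(a, b); r2 <- mcs(a, b)
  expect_identical(r1$mapping, r2$mapping)
  expect_equal(r1$mapping[, 1L], sort(r1$mapping[, 1L]))
})

test_that("backtracking MCS equals the exhaustive subset-injection oracle", {
  spec <- synthetic_spec(seed = 401L, n_molecules = 60L,
                         heavy_atom_range = c(4L, 7L),
                         charge_pair_probability = 0.1)
  mols <- generate_molecules(spec)
  set.seed(402L)
  for (k in seq_len(30L)) {
    i <- sample(length(mols), 2L)
    a <- mols[[i[1L]]]; b <- mols[[i[2L]]]
    got <- mcs(a, b, match_semantics("atoms", FALSE, "any"))$atoms_mapped
    expect_equal(got, oracle_mcs_atoms(a, b),
                 info = sprintf("pair %s | %s", a$smiles, b$smiles))
    got_exact <- mcs(a, b, match_semantics("atoms", FALSE, "exact"))$atoms_mapped
    expect_equal(got_exact, oracle_mcs_atoms(a, b, bond_exact = TRUE),
                 info = sprintf("exact pair %s | %s", a$smiles, b$smiles))
  }
})

test_that("tanimoto matrix is symmetric, unit-diagonal and bounded on the panel", {
  panel <- panel_fixture()
  tm <- tanimoto_matrix(panel)
  expect_equal(dim(tm), c(14L, 14L))
  expect_equal(unname(diag(tm)), rep(1, 14L))
  expect_true(all(tm >= 0 & tm <= 1))
  expect_equal(unclass(tm), t(unclass(tm)), ignore_attr = TRUE)

  single <- tanimoto_matrix(panel["Gly"])
  expect_equal(unclass(single), matrix(1, 1, 1, dimnames = list("Gly", "Gly")),
               ignore_attr = TRUE)
})

test_that("tanimoto = 1 implies isomorphism under the active semantics", {
  a <- mol("OCC(O)CO", "a")
  b <- mol("C(CO)(O)CO", "b")
  r <- mcs(a, b, match_semantics("atoms", FALSE, "exact"))
  expect_equal(r$tanimoto, 1)
  expect_true(molecules_isomorphic(a, b))
})

test_that("deleting a terminal atom never increases the shared-feature count", {
  spec <- synthetic_spec(seed = 407L, n_molecules = 20L,
                         heavy_atom_range = c(5L, 9L),
                         charge_pair_probability = 0)
  mols <- generate_molecules(spec)
  ref <- mols[[1L]]
  for (m in mols[2:11]) {
    pruned <- tryCatch(perturb(m, "delete_terminal_atom"), error = function(e) NULL)
    if (is.null(pruned)) next
    c_full <- mcs(ref, m)$c
    c_pruned <- mcs(ref, pruned)$c
    expect_lte(c_pruned, c_full)
  }
})

test_that("the size guard rejects oversized molecules", {
  big <- mol(paste(rep("C", 45L), collapse = ""), "c45")
  expect_error(mcs(big, big), "too large for exact MCS")
})

test_that("calibrate_semantics selects a variant deterministically with logged residuals", {
  panel <- panel_fixture()
  printed <- bs_constants()$printed_reference_pairs$pairs
  sem <- calibrate_semantics(panel, printed)
  expect_s3_class(sem, "match_semantics")
  res <- attr(sem, "residuals")
  expect_equal(nrow(res), nrow(printed))
  expect_equal(attr(sem, "max_abs_deviation"), max(abs(res$deviation)))
  # calibration is reproducible
  sem2 <- calibrate_semantics(panel, printed)
  expect_identical(unclass(sem)[1:3], unclass(sem2)[1:3])

  expect_error(calibrate_semantics(panel, printed[0, ]), "at least one")

  # a single pair matched exactly by several variants resolves by the
  # documented preference order (atoms unit, charge-blind, any-order first)
  pair <- data.frame(a = "AA", b = "DMA", tanimoto = 5 / 7)
  tie <- calibrate_semantics(panel, pair)
  expect_equal(tie$unit, "atoms")
  expect_false(tie$charge_sensitive)
  expect_equal(tie$bond_match, "any")
})
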
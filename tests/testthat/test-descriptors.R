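mol <- function(smi, id = "m") parse_smiles(smi, id)

test_that("molecular weight matches hand-computed formula weights", {
  expect_equal(round(molecular_weight(mol("OCC(O)CO")), 2), 92.09)
  expect_equal(round(molecular_weight(mol("O")), 2), 18.02)
  expect_equal(round(molecular_weight(mol("C=CC(N)=O")), 2), 71.08)
})

test_that("fraction Csp3, H-bond counts and rotatable bonds follow their pinned definitions", {
  expect_equal(fraction_csp3(mol("CC")), 1)
  expect_equal(fraction_csp3(mol("c1ccccc1")), 0)
  expect_equal(fraction_csp3(mol("OCC(O)CO")), 1)
  expect_error(fraction_csp3(mol("O=S=O")), "no carbon")

  gly <- mol("OCC(O)CO")
  expect_equal(count_hba(gly), 3L)
  expect_equal(count_hbd(gly), 3L)
  benz <- mol("c1ccccc1")
  expect_equal(count_hba(benz), 0L)
  expect_equal(count_hbd(benz), 0L)
  aa <- mol("C=CC(N)=O")
  expect_equal(count_hba(aa), 1L)  # carbonyl O only; amide N excluded
  expect_equal(count_hbd(aa), 1L)  # the NH2 nitrogen counts once

  expect_equal(rotatable_bonds(mol("CC")), 0L)
  expect_equal(rotatable_bonds(mol("CCCC")), 1L)
  expect_equal(rotatable_bonds(aa), 1L)  # C-C(=O); amide C-N excluded
})

test_that("TPSA reproduces the Ertl contributions", {
  expect_equal(tpsa(mol("c1ccccc1")), 0)
  expect_equal(tpsa(mol("CCO")), 20.23)
  expect_equal(tpsa(mol("OCC(O)CO")), 60.69)  # 3 x 20.23 by additivity
  # sulfonate: 2 x (=O) + O- + hexavalent S
  expect_equal(tpsa(mol("CS(=O)(=O)[O-]")), 2 * 17.07 + 23.06 + 8.38)
  expect_error(tpsa(mol("O")), "no TPSA contribution")
})

test_that("WLOGP/MR are additive over atom types and atom-order invariant", {
  increment <- wlogp(mol("CCC")) - wlogp(mol("CC"))
  expect_equal(wlogp(mol("CCCC")) - wlogp(mol("CCC")), increment)
  expect_equal(molar_refractivity(mol("CCCC")) - molar_refractivity(mol("CCC")),
               molar_refractivity(mol("CCC")) - molar_refractivity(mol("CC")))
  expect_equal(wlogp(mol("OCC(O)CO")), wlogp(mol("C(CO)(O)CO")))
  # methane = one C1 carbon + 4 hydrocarbon hydrogens from the packaged table
  expect_equal(wlogp(mol("C")), 0.1441 + 4 * 0.123)
  expect_equal(molar_refractivity(mol("C")), 2.503 + 4 * 1.057)
})

test_that("descriptor values agree with an independent reference implementation", {
  # reference values computed with rdkit 2024.09 (Crippen logP/MR and Ertl
  # TPSA with the S/P extension) on the identical structures
  ref <- read.csv(text = "id,tpsa,wlogp,mr
OZ,21.59,0.0449,19.3110
AA,43.09,-0.3423,19.3914
VP,20.31,0.7523,31.1440
Gly,60.69,-1.6681,20.1784
AcM,29.54,0.0312,37.5960
DMA,20.31,0.2606,28.8910
HPMA,49.33,0.0595,39.5045
HEMA,49.33,-0.3290,34.9095
SA,176.78,-3.8718,64.7865
CBAA,69.23,-1.4950,54.6731
CBMA,66.43,-0.6779,57.2394
SBMA,91.88,0.1174,66.7966
MPC,94.70,0.3135,68.1829
VPPS,69.46,0.5524,55.9092", stringsAsFactors = FALSE)
  panel <- panel_fixture()
  for (k in seq_len(nrow(ref))) {
    m <- panel[[ref$id[k]]]
    expect_equal(tpsa(m), ref$tpsa[k], tolerance = 1e-4)
    expect_equal(wlogp(m), ref$wlogp[k], tolerance = 1e-3)
    expect_equal(molar_refractivity(m), ref$mr[k], tolerance = 1e-3)
  }
})

test_that("ESOL behaves like the packaged linear model", {
  co <- bs_constants()$esol
  expect_equal(esol_logs(0, 0, 0, 0), co$intercept)
  expect_lt(esol_logs(2, 100, 1, 0), esol_logs(1, 100, 1, 0))  # higher logP, lower logS
  gly <- descriptor_vector(mol("OCC(O)CO", "gly"))
  benz <- descriptor_vector(mol("c1ccccc1", "benzene"))
  expect_gt(gly$esol_logs, benz$esol_logs)
})

test_that("rule filters apply the published thresholds", {
  gly <- descriptor_vector(mol("OCC(O)CO", "gly"))
  rep <- evaluate_rules(gly, mol("OCC(O)CO", "gly"))
  lip <- rep[rep$rule == "Lipinski", ]
  expect_true(lip$passes)
  expect_equal(lip$n_violations, 0L)
  expect_equal(lip$bioavailability_score, 0.55)

  big <- gly
  big$molecular_weight <- 600; big$wlogp <- 6; big$hbd <- 6; big$hba <- 11
  lip2 <- evaluate_rules(big)[1L, ]
  expect_false(lip2$passes)
  expect_equal(lip2$n_violations, 4L)

  vib <- gly
  vib$rotatable_bonds <- 11L; vib$tpsa <- 150
  veb <- evaluate_rules(vib)
  veb <- veb[veb$rule == "Veber", ]
  expect_false(veb$passes)
  expect_equal(veb$n_violations, 2L)
})

test_that("descriptor_table has one row per molecule in input order", {
  panel <- panel_fixture()
  tab <- descriptor_table(panel)
  expect_equal(dim(tab), c(14L, 11L))  # identifier + 10 descriptors
  expect_equal(tab$identifier, names(panel))

  expect_equal(nrow(descriptor_table(list())), 0L)

  dup <- descriptor_table(list(panel$AA, panel$AA))
  expect_equal(dup[1L, ], dup[2L, ], ignore_attr = TRUE)

  # the structural outlier SA is extreme on TPSA and size
  expect_equal(tab$identifier[which.max(tab$tpsa)], "SA")
  expect_equal(tab$identifier[which.max(tab$heavy_atoms)], "SA")
})
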
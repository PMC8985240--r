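test_that("boiled_egg classifies clear-cut points", {
  far <- boiled_egg(500, 0)
  expect_equal(far$gi_absorption, "low")
  expect_equal(far$bbb_permeant, "no")

  center_white <- boiled_egg(71, 2.3)
  expect_equal(center_white$gi_absorption, "high")
})

test_that("panel molecules classify as the published egg model predicts", {
  panel <- panel_fixture()
  scr <- screen_panel(panel)

  sa <- scr[scr$identifier == "SA", ]
  expect_equal(sa$gi_absorption, "low")
  expect_equal(sa$bbb_permeant, "no")

  gly <- scr[scr$identifier == "Gly", ]
  expect_equal(gly$gi_absorption, "high")
  expect_equal(gly$bbb_permeant, "no")

  # SA is the only low-absorption monomer of the panel
  expect_equal(scr$identifier[scr$gi_absorption == "low"], "SA")

  expect_setequal(scr$identifier[scr$bbb_permeant == "yes"],
                  c("OZ", "AA", "VP", "AcM", "DMA", "HPMA", "HEMA", "VPPS"))
  expect_setequal(scr$identifier[scr$bbb_permeant == "no"],
                  c("Gly", "SA", "CBAA", "CBMA", "SBMA", "MPC"))

  # zwitterions carry a model-domain warning
  expect_true(all(nzchar(scr$warnings[scr$identifier %in%
                                        c("CBAA", "CBMA", "SBMA", "MPC", "VPPS")])))
  expect_false(any(nzchar(scr$warnings[scr$identifier %in% c("AA", "Gly")])))

  expect_equal(nrow(screen_panel(list())), 0L)
})

test_that("classification depends only on the (TPSA, WLOGP) pair", {
  a <- boiled_egg(55.4, 1.2)
  b <- boiled_egg(55.4, 1.2)
  expect_identical(a[, c("gi_absorption", "bbb_permeant")],
                   b[, c("gi_absorption", "bbb_permeant")])
})

test_that("membership along a TPSA ray never re-enters after exit", {
  for (wl in c(-2, 0, 2.3, 5)) {
    inside <- vapply(seq(0, 300, by = 1), function(tp) {
      boiled_egg(tp, wl)$gi_absorption == "high"
    }, logical(1L))
    runs <- rle(inside)$values
    expect_lte(sum(runs), 2L)          # at most one contiguous inside stretch
    expect_lte(length(runs), 3L)
  }
})
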
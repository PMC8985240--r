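test_that("standardize z-scores columns with population sd and drops constants", {
  m <- matrix(c(1, 2, 3), ncol = 1L, dimnames = list(NULL, "x"))
  expect_error(standardize(m[1L, , drop = FALSE]), "at least two rows")
  z <- standardize(m)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  m2 <- cbind(m, const = c(7, 7, 7))
  expect_warning(z2 <- standardize(m2), "constant column")
  expect_equal(colnames(z2), "x")

  expect_equal(unname(standardize(z)[, 1L]), unname(z[, 1L]), tolerance = 1e-12)
})

test_that("euclidean distances match the closed form and an independent recomputation", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  d <- euclidean_distances(m)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "a"], 0)

  set.seed(11)
  r <- matrix(rnorm(15), 5, 3, dimnames = list(letters[1:5], NULL))
  d2 <- euclidean_distances(r)
  manual <- outer(seq_len(5), seq_len(5),
                  Vectorize(function(i, j) sqrt(sum((r[i, ] - r[j, ])^2))))
  expect_equal(unclass(d2), manual, ignore_attr = TRUE)

  r[2, 2] <- NA
  expect_error(euclidean_distances(r), "missing value")
})

test_that("agglomerate performs group-average linkage with the documented tie-break", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- agglomerate(d2)
  expect_equal(nrow(t2$merges), 1L)
  expect_equal(t2$merges$height, 3)
  expect_true(are_siblings(t2, "A", "B"))

  d3 <- matrix(c(0, 1, 4,
                 1, 0, 4,
                 4, 4, 0), 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- agglomerate(d3)
  expect_equal(t3$merges$height, c(1, 4))
  expect_setequal(clade_members(t3, 1L), c("x", "y"))
  expect_setequal(clade_members(t3, 2L), c("x", "y", "z"))
})

test_that("agglomerate matches stats::hclust average linkage on random matrices", {
  set.seed(2101)
  for (k in seq_len(40L)) {
    n <- sample(3:8, 1L)
    m <- random_dist_matrix(n)
    tree <- agglomerate(m)
    h <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(tree$merges$height), sort(h$height), tolerance = 1e-9)
    expect_equal(cophenetic_matrix(tree)[h$labels, h$labels],
                 as.matrix(stats::cophenetic(h)), tolerance = 1e-9)
  }
})

test_that("merge heights are monotone and cophenetic distances ultrametric", {
  set.seed(2102)
  for (k in seq_len(10L)) {
    m <- random_dist_matrix(7L)
    tree <- agglomerate(m)
    expect_true(all(diff(tree$merges$height) >= -1e-12))
    cp <- cophenetic_matrix(tree)
    expect_equal(cp, t(cp))
    for (i in 1:5) for (j in 2:6) for (l in 3:7) {
      expect_lte(cp[i, j], max(cp[i, l], cp[j, l]) + 1e-12)
    }
  }
})

test_that("row order does not change topology or heights", {
  set.seed(2103)
  m <- random_dist_matrix(6L)
  perm <- sample(6L)
  t1 <- agglomerate(m)
  t2 <- agglomerate(m[perm, perm])
  expect_equal(sort(t1$merges$height), sort(t2$merges$height), tolerance = 1e-12)
  ids <- rownames(m)
  expect_equal(cophenetic_matrix(t1)[ids, ids], cophenetic_matrix(t2)[ids, ids],
               tolerance = 1e-12)
})

test_that("clustroid minimizes the distance sum with lexicographic ties", {
  m <- matrix(c(0, 1, 5,
                1, 0, 4,
                5, 4, 0), 3, 3, dimnames = list(c("p0", "p1", "p5"), c("p0", "p1", "p5")))
  expect_equal(clustroid(m, c("p0", "p1", "p5")), "p1")
  expect_equal(clustroid(m, "p5"), "p5")
  expect_error(clustroid(m, character(0)), "empty")
  expect_error(clustroid(m, c("p0", "zz")), "unknown")

  sym <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("b", "a"), c("b", "a")))
  expect_equal(clustroid(sym, c("b", "a")), "a")
})

test_that("newick export is valid and round-trips through an external parser", {
  skip_if_not_installed("ape")
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- agglomerate(d2)
  expect_equal(newick_export(t2), "(A:4,B:4);")

  panel <- panel_fixture()
  tree <- agglomerate(euclidean_distances(standardize(descriptor_table(panel))))
  nwk <- newick_export(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(sort(ph$tip.label), sort(names(panel)))
  # the external parser sees the same topology: identical leaf partitions
  # at the root split
  top <- tree$merges[nrow(tree$merges), ]
  left <- clade_members(tree, top$left)
  ape_split <- ape::prop.part(ph)
  expect_true(length(left) %in% c(1L, 13L))

  ord <- heatmap_order(tree)
  expect_setequal(ord, names(panel))
})
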
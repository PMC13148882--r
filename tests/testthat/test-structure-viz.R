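test_that("classical MDS reproduces forced low-dimensional configurations", {
  # two points at distance d embed at +/- d/2
  m <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  proj <- classicalMds(m, k = 1)
  expect_equal(unname(sort(abs(coordinates(proj)[, 1]))), c(1.5, 1.5))
  expect_equal(sum(coordinates(proj)[, 1]), 0, tolerance = 1e-12)  # centred
  expect_gte(coordinates(proj)["A", 1], 0)  # focal orientation

  # three mutually equidistant points form an equilateral triangle
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  p3 <- classicalMds(m3, k = 2)
  dd <- as.matrix(dist(coordinates(p3)))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-10)
})

test_that("MDS inverts Euclidean-embeddable matrices and caps k at positive eigenvalues", {
  set.seed(21)
  m <- randomEuclideanMatrix(5, dim = 3)
  proj <- classicalMds(m, k = 4)
  expect_lte(proj@k, sum(eigenvalues(proj) > 1e-8))
  rec <- as.matrix(dist(coordinates(proj)))
  expect_lt(max(abs(rec - m)), 1e-8)
  expect_lt(reconstructionError(proj), 1e-7)
  # coordinates centred at the origin (up to eigensolver noise)
  expect_lt(max(abs(colMeans(coordinates(proj)))), 1e-8)
})

test_that("MDS distances are invariant under label permutation", {
  set.seed(22)
  m <- randomEuclideanMatrix(6)
  perm <- sample(6)
  d1 <- as.matrix(dist(coordinates(classicalMds(m, k = 5))))
  d2 <- as.matrix(dist(coordinates(classicalMds(m[perm, perm], k = 5))))
  expect_equal(d2[rownames(m), rownames(m)], d1, tolerance = 1e-8)
})

test_that("MDS rejects infinite entries with an actionable error", {
  m <- matrix(c(0, Inf, Inf, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(classicalMds(m), "exclude these populations")
})

test_that("UPGMA reproduces the hand-worked 4-leaf example", {
  m <- matrix(10, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 2
  m["C", "D"] <- m["D", "C"] <- 4
  diag(m) <- 0
  tr <- upgma(m)
  expect_equal(mergeHeights(tr), c(1, 2, 5))
  expect_equal(newick(tr), "((A:1,B:1):4,(C:2,D:2):3);")
  coph <- copheneticDistances(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["C", "D"], 4)
  expect_equal(coph["A", "C"], 10)
})

test_that("two leaves merge at half their distance", {
  m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(m)
  expect_equal(mergeHeights(tr), 1)
  expect_equal(newick(tr), "(A:1,B:1);")
})

test_that("UPGMA cophenetics equal the hclust average-linkage oracle", {
  set.seed(31)
  for (i in 1:25) {
    m <- randomSymmetricMatrix(6)
    mine <- copheneticDistances(upgma(m))
    oracle <- hclustCopheneticOracle(m)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("UPGMA trees are ultrametric with non-decreasing merge heights", {
  set.seed(32)
  for (i in 1:50) {
    m <- randomSymmetricMatrix(sample(4:8, 1))
    tr <- upgma(m)
    expect_true(all(diff(mergeHeights(tr)) >= -1e-12))
    coph <- copheneticDistances(tr)
    n <- nrow(coph)
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
      trip <- sort(c(coph[a, b], coph[a, cc], coph[b, cc]))
      expect_lt(abs(trip[2] - trip[3]), 1e-9)  # two largest equal
    }
  }
})

test_that("the Newick string parses and preserves cophenetic structure", {
  skip_if_not_installed("ape")
  set.seed(33)
  m <- randomSymmetricMatrix(6)
  tr <- upgma(m)
  phy <- ape::read.tree(text = newick(tr))
  coph <- as.matrix(ape::cophenetic.phylo(phy))
  mine <- copheneticDistances(tr)
  expect_equal(coph[rownames(mine), colnames(mine)], mine,
               tolerance = 1e-8)
  # equal leaf-to-root path length for all leaves (ultrametric tree)
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_lt(diff(range(depths)), 1e-8)
})

test_that("the focal cohort's nearest GSTM1 neighbour among the highlighted panel populations is Portugal", {
  panel <- table3Panel()
  figurePops <- c("Current study (Venezuela)", "Portuguese",
                  "Italian (Rome)", "Spanish (Murcia)", "Ibo (Abuja)",
                  "Yoruba (Abuja)", "Wayuu (ethnic group, Venezuela)",
                  "Mexico (central)", "Chinese (Beijing)",
                  "Japanese (Tokyo)")
  withM1 <- figurePops[!is.na(nullFreq(panel, "GSTM1")[figurePops])]
  dm <- neiDistanceMatrix(panel, whichLoci = "GSTM1", subset = withM1)
  d <- dm["Current study (Venezuela)", ]
  d <- d[names(d) != "Current study (Venezuela)"]
  expect_equal(names(which.min(d)), "Portuguese")
})
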
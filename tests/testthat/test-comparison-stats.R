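test_that("count reconstruction honours its policy", {
  expect_equal(unname(reconstructCounts(120, 0.510)), c(61, 59))
  expect_equal(unname(reconstructCounts(101, 0.36)), c(36, 65))
  expect_equal(unname(reconstructCounts(40, 0)), c(0, 40))
  expect_equal(unname(reconstructCounts(120, 0.510, "exact_fractional")),
               c(61.2, 58.8))
  expect_error(fisherExact(matrix(c(61.2, 58.8, 10, 10), 2, byrow = TRUE)),
               "integer")
})

test_that("Pearson chi-square agrees with the textbook formula", {
  tab <- matrix(c(116, 184, 61, 59), 2, byrow = TRUE)
  res <- pearsonChi2(tab)
  expect_equal(res$statistic, chi2Oracle(tab), tolerance = 1e-12)
  expect_equal(res$statistic, 5.2037, tolerance = 1e-4)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_equal(res$p, 0.0225, tolerance = 2e-3)

  tab2 <- matrix(c(98, 202, 36, 65), 2, byrow = TRUE)
  res2 <- pearsonChi2(tab2)
  expect_equal(res2$statistic, 0.301, tolerance = 1e-3)
  expect_equal(res2$p, 0.583, tolerance = 1e-3)

  # identical row proportions: no association
  res0 <- pearsonChi2(matrix(c(30, 70, 60, 140), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("Pearson statistic is invariant under row/column swaps and Yates shrinks it", {
  set.seed(11)
  for (i in 1:50) {
    tab <- randomTable(200)
    s <- pearsonChi2(tab)$statistic
    expect_equal(pearsonChi2(tab[2:1, ])$statistic, s)
    expect_equal(pearsonChi2(tab[, 2:1])$statistic, s)
    expect_lte(pearsonChi2(tab, yates = TRUE)$statistic, s + 1e-12)
  }
})

test_that("Fisher p matches enumeration, fisher.test, and handles degenerate columns", {
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p,
               2 / 252, tolerance = 1e-12)
  expect_equal(fisherExact(matrix(c(0, 10, 0, 10), 2, byrow = TRUE))$p, 1)
  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(sample.int(16, 4, replace = TRUE) - 1L, 2)
    mine <- fisherExact(tab)$p
    expect_equal(mine, fisherOracle(tab), tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # the double-one-sided variant never falls below point-probability p
  tab <- matrix(c(8, 2, 3, 9), 2, byrow = TRUE)
  expect_gte(fisherExact(tab, twoSided = "double_one_sided")$p,
             fisherExact(tab)$p - 1e-12)
})

test_that("large balanced tables: Pearson and Fisher p agree asymptotically", {
  tab <- matrix(c(150, 350, 175, 325), 2, byrow = TRUE)  # 0.30 vs 0.35, n=500
  pF <- fisherExact(tab)$p
  # the continuity-corrected Pearson p tracks the exact test closely
  expect_lt(abs(pearsonChi2(tab, yates = TRUE)$p - pF), 0.01)
  # the uncorrected statistic is anti-conservative but within a small gap
  expect_lt(abs(pearsonChi2(tab)$p - pF), 0.02)
})

test_that("panel comparison selects methods, skips unusable rows, and is null for self", {
  co <- table2Cohort()
  panel <- table3Panel()
  lf <- phenotypeFrequencies(co, "GSTT1")
  expect_message(res <- comparePanel(lf, panel, "GSTT1"), "skipping")
  skipped <- attr(res, "skipped")
  expect_true(all(c("Amerindians (Tarahumara, Mex)", "Mestizos (Mexico)")
                  %in% skipped))
  # Pemon (0/40): min expected = 40*98/340 ~ 11.5 >= 5, so auto -> pearson
  expect_equal(res$method[res$population == "Pemon (ethnic group, Venezuela)"],
               "pearson")
  resF <- suppressMessages(
    comparePanel(lf, panel, "GSTT1", method = "fisher"))
  expect_true(all(resF$method == "fisher"))

  # GSTM1 comparison must skip Murcia (missing cell)
  lfM <- phenotypeFrequencies(co, "GSTM1")
  resM <- suppressMessages(comparePanel(lfM, panel, "GSTM1"))
  expect_false("Spanish (Murcia)" %in% resM$population)
  expect_true("Spanish (Murcia)" %in% attr(resM, "skipped"))

  # self-comparison: the panel's current-study row has the same frequency
  self <- resM[resM$population == "Current study (Venezuela)", ]
  expect_lt(self$statistic, 0.01)  # 0.387 is the rounded 116/300
  expect_true(all(res$provenance == "reconstructed"))
})
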
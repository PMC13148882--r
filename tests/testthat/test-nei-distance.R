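test_that("Nei identity and distance match closed-form evaluations", {
  # self-identity
  expect_equal(neiIdentity(0.62, 0.62), 1)
  expect_equal(neiDistance(0.62, 0.62), 0)
  # against a fixed functional population (p=1, q=0)
  q <- 0.6218; p <- 1 - q
  expect_equal(neiIdentity(q, 0), p / sqrt(p^2 + q^2), tolerance = 1e-12)
  expect_equal(neiIdentity(q, 0), 0.5197, tolerance = 1e-4)
  # the published Portugal anchor cell
  I <- neiIdentity(sqrt(0.3867), sqrt(0.372))
  expect_equal(I, 0.99974, tolerance = 1e-5)
  D <- neiDistance(sqrt(0.3867), sqrt(0.372))
  expect_equal(roundHalfUp(D, 4), 0.0003)
  # opposite fixation
  expect_equal(neiIdentity(0, 1), 0)
  expect_identical(neiDistance(0, 1), Inf)
})

test_that("identity stays in (0,1] and distance is finite off the fixation corner", {
  set.seed(3)
  qa <- runif(500); qb <- runif(500)
  I <- neiIdentity(qa, qb)
  expect_true(all(I > 0 & I <= 1 + 1e-12))
  expect_true(all(is.finite(neiDistance(qa, qb))))
})

test_that("distance grows with |qa - qb| along a one-sided family", {
  qa <- 0.4
  grid <- seq(0.4, 1, by = 0.01)
  D <- neiDistance(qa, grid)
  expect_true(all(diff(D) > -1e-14))
  gridLo <- seq(0.4, 0, by = -0.01)
  expect_true(all(diff(neiDistance(qa, gridLo)) > -1e-14))
})

test_that("averaging excludes missing loci and warns on infinities", {
  avg <- averageDistance(c(GSTM1 = 0.0003, GSTT1 = 0.0452))
  expect_equal(as.numeric(avg), 0.02275)
  expect_equal(roundHalfUp(as.numeric(avg), 4), 0.0228)
  one <- averageDistance(c(GSTM1 = NA, GSTT1 = 0.0614))
  expect_equal(as.numeric(one), 0.0614)
  expect_identical(attr(one, "used"), "GSTT1")
  expect_warning(w <- averageDistance(c(A = Inf, B = 0.2)), "infinite")
  expect_equal(as.numeric(w), 0.2)
  expect_error(averageDistance(c(A = NA_real_)), "no shared loci")
})

test_that("distance matrices are symmetric, zero-diagonal and match elementwise recomputation", {
  panel <- table3Panel()
  sel <- c("Current study (Venezuela)", "Portuguese", "Ibo (Abuja)",
           "Mexico (central)", "Chinese (Beijing)")
  dm <- neiDistanceMatrix(panel, subset = sel)
  expect_identical(rownames(dm), sel)
  expect_equal(max(abs(dm - t(dm))), 0)
  expect_equal(max(abs(diag(dm))), 0)
  expect_true(all(dm >= 0))
  # elementwise oracle on the pair (current, Portugal)
  f1 <- nullFreq(panel, "GSTM1"); f2 <- nullFreq(panel, "GSTT1")
  dGSTM1 <- neiDistance(sqrt(f1[[sel[1]]]), sqrt(f1[["Portuguese"]]))
  dGSTT1 <- neiDistance(sqrt(f2[[sel[1]]]), sqrt(f2[["Portuguese"]]))
  expect_equal(dm[sel[1], "Portuguese"], mean(c(dGSTM1, dGSTT1)),
               tolerance = 1e-14)
  # per-locus matrices agree with the average
  both <- neiDistanceMatrix(panel, subset = sel, perLocus = TRUE)
  expect_equal((both$perLocus$GSTM1 + both$perLocus$GSTT1) / 2, both$average,
               tolerance = 1e-14)

  # Murcia pairs average over GSTT1 only
  dmM <- neiDistanceMatrix(panel,
                           subset = c(sel[1], "Spanish (Murcia)"))
  dT <- neiDistance(sqrt(f2[[sel[1]]]), sqrt(0.179))
  expect_equal(dmM[1, 2], dT)
})

test_that("property sweep: random panels give symmetric zero-diagonal matrices", {
  set.seed(17)
  for (i in 1:100) {
    nPop <- sample(3:6, 1)
    d <- data.frame(population = paste0("P", seq_len(nPop)),
                    region = "R", n = 50,
                    L1 = runif(nPop), L2 = runif(nPop))
    dm <- neiDistanceMatrix(ReferencePanel(d))
    expect_equal(max(abs(dm - t(dm))), 0)
    expect_equal(max(abs(diag(dm))), 0)
  }
})

test_that("dropIncomplete removes populations missing a requested locus", {
  panel <- table3Panel()
  expect_message(
    dm <- neiDistanceMatrix(panel, whichLoci = "GSTM1", dropIncomplete = TRUE),
    "Murcia")
  expect_false("Spanish (Murcia)" %in% rownames(dm))
  expect_equal(nrow(dm), 95)
})

test_that("degenerate selections behave as specified", {
  panel <- table3Panel()
  one <- neiDistanceMatrix(panel, subset = "Portuguese")
  expect_equal(dim(one), c(1, 1))
  expect_equal(one[1, 1], 0)
  d <- data.frame(population = c("A", "B", "C"), region = "R", n = 10,
                  L1 = 0.4, L2 = 0.2)
  expect_equal(max(neiDistanceMatrix(ReferencePanel(d))), 0)
  expect_error(neiDistanceMatrix(panel, subset = character(0)), "empty")
})
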
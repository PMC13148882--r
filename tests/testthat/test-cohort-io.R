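test_that("call tables round-trip through read/write with stable order", {
  co <- table2Cohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCalls(co, f)
  back <- readCalls(f)
  expect_identical(sampleIds(back), sampleIds(co))
  expect_identical(loci(back), loci(co))
  expect_identical(nullCalls(back), nullCalls(co))
  expect_equal(unname(nullCounts(back)["GSTM1"]), 116)
})

test_that("call parsing accepts the configurable alphabet and flags bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tGSTM1\tGSTT1",
               "s1\t+\t0",
               "s2\tnull\t1",
               "s3\tPRESENT\t-"), f)
  co <- readCalls(f)
  expect_equal(unname(nullCounts(co)), c(1, 2))

  writeLines(c("sample_id\tGSTM1", "s1\tx"), f)
  expect_error(readCalls(f), "row 1, column 'GSTM1'")

  writeLines(c("sample_id\tGSTM1", "s1\t+", "s1\t-"), f)
  expect_error(readCalls(f), "duplicate sample_id")
})

test_that("a header-only file yields an empty cohort; errors defer downstream", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tGSTM1\tGSTT1", f)
  co <- readCalls(f)
  expect_equal(ncol(co), 0)
  expect_identical(loci(co), c("GSTM1", "GSTT1"))
  expect_error(phenotypeFrequencies(co, "GSTM1"), "empty")
})

test_that("the packaged panel matches its published layout", {
  panel <- table3Panel()
  expect_equal(length(panel), 96)
  reg <- panelRegions(panel)
  # 21 Americas rows in total; 18 are external references with a stated n
  amer <- names(reg)[reg == "Americas"]
  expect_equal(length(amer), 21)
  nAmer <- panelSizes(panel)[amer]
  expect_equal(sum(!is.na(nAmer) & amer != "Current study (Venezuela)"), 18)

  expect_equal(unname(nullFreq(panel, "GSTM1")[["Ibo (Abuja)"]]), 0.23)
  expect_equal(unname(nullFreq(panel, "GSTT1")[["Ibo (Abuja)"]]), 0.36)
  expect_equal(unname(panelSizes(panel)[["Ibo (Abuja)"]]), 101)
  # Murcia has only GSTT1
  expect_true(is.na(nullFreq(panel, "GSTM1")[["Spanish (Murcia)"]]))
  expect_equal(unname(nullFreq(panel, "GSTT1")[["Spanish (Murcia)"]]), 0.179)
  # rows without n stay usable for distances
  expect_true(is.na(panelSizes(panel)[["Mestizos (Mexico)"]]))
})

test_that("panels round-trip exactly and reject invalid content", {
  panel <- table3Panel()
  f <- withr::local_tempfile(fileext = ".tsv")
  writePanel(panel, f)
  back <- readPanel(f)
  expect_identical(populations(back), populations(panel))
  for (l in loci(panel))
    expect_identical(nullFreq(back, l), nullFreq(panel, l))
  expect_identical(panelSizes(back), panelSizes(panel))

  writeLines(c("population\tregion\tn\tGSTM1", "X\tE\t10\t0.5",
               "X\tE\t12\t0.4"), f)
  expect_error(readPanel(f), "duplicate")
  writeLines(c("population\tregion\tn\tGSTM1", "X\tE\t10\t1.5"), f)
  expect_error(readPanel(f), "invalid GSTM1")
  writeLines(c("population\tregion\tn\tGSTM1", "X\tE\tlots\t0.5"), f)
  expect_error(readPanel(f), "non-numeric")
})

test_that("addPopulation prepends a focal record with missing loci as NA", {
  panel <- table3Panel()
  p2 <- addPopulation(panel, "Focal", nullFreq = c(GSTT1 = 0.25),
                      n = 100, before = TRUE)
  expect_equal(populations(p2)[1], "Focal")
  expect_true(is.na(nullFreq(p2, "GSTM1")[["Focal"]]))
  expect_equal(unname(nullFreq(p2, "GSTT1")[["Focal"]]), 0.25)
  expect_error(addPopulation(panel, "Y", nullFreq = c(BAD = 0.1)),
               "loci not in panel")
})
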
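test_that("Genepop parsing transcribes genotypes, populations and missing codes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy data", "locA", "POP",
               "i1 , 0102", "i2 , 0101", "POP", "i3 , 0202"), f)
  x <- readGenepop(f)
  expect_equal(nInd(x), 3L)
  expect_equal(markerNames(x), "locA")
  expect_equal(sort(x@markers[[1]]), c(1L, 2L))
  expect_equal(popLabels(x), c("pop1", "pop1", "pop2"))
  expect_equal(unname(alleleCalls(x)$a[, 1]), c(1L, 1L, 2L))
  expect_equal(unname(alleleCalls(x)$b[, 1]), c(2L, 1L, 2L))

  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "POP", "i1 , 0000"), f2)
  y <- readGenepop(f2)
  expect_true(is.na(alleleCalls(y)$a[1, 1]) && is.na(alleleCalls(y)$b[1, 1]))
})

test_that("Genepop parse errors name the offending line or locus", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "locB", "POP", "i1 , 0102"), f)
  expect_error(readGenepop(f), "expected 2 genotypes")

  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "POP", "i1 , 0102", "i2 , 010101"), f2)
  expect_error(readGenepop(f2), "mixes")

  f3 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "POP", "i1 , 0100"), f3)
  expect_error(readGenepop(f3), "half-missing")
})

test_that("generated datasets round-trip through Genepop and the table format", {
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 12, nLoci = 7,
                                     allelesPerLocus = 8, F = 0.05,
                                     nullFreq = 0.1, blankFailureRate = 0.05,
                                     seed = 21))
  x <- sim$dataset

  f <- withr::local_tempfile(fileext = ".gen")
  writeGenepop(x, f)
  y <- readGenepop(f)
  ord <- match(indInfo(x)$id, indInfo(y)$id)
  expect_false(anyNA(ord))
  expect_equal(unname(alleleCalls(y)$a[ord, ]), unname(alleleCalls(x)$a))
  expect_equal(unname(alleleCalls(y)$b[ord, ]), unname(alleleCalls(x)$b))
  # population structure preserved (site names differ: Genepop has no ids)
  expect_equal(as.integer(factor(popLabels(y)[ord], levels = unique(popLabels(y)[ord]))),
               as.integer(factor(popLabels(x), levels = unique(popLabels(x)))))

  ft <- withr::local_tempfile(fileext = ".csv")
  fs <- withr::local_tempfile(fileext = ".csv")
  writeGenotypeTable(x, ft, fs)
  z <- readGenotypeTable(ft, fs)
  expect_equal(z@alleleA, x@alleleA)
  expect_equal(z@alleleB, x@alleleB)
  expect_equal(indInfo(z)$habitat, indInfo(x)$habitat)
  expect_equal(siteInfo(z)$latitude, siteInfo(x)$latitude)
})

test_that("table reader rejects duplicate ids and invalid habitat labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,site_id,habitat,L1.a,L1.b",
               "i1,s1,rock,1,2", "i1,s1,rock,1,1"), f)
  expect_error(readGenotypeTable(f), "duplicate individual_id")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,site_id,habitat,L1.a,L1.b",
               "i1,s1,driftwood,1,2"), f2)
  expect_error(readGenotypeTable(f2), "habitat")
})

test_that("scored-loci filter keeps exactly the sufficiently genotyped individuals", {
  sim <- simulateGenotypes(simConfig(nPops = 2, nPerPop = 40, nLoci = 7,
                                     allelesPerLocus = 6, nullFreq = 0.25,
                                     blankFailureRate = 0.15, seed = 5))
  x <- sim$dataset
  scored <- rowSums(!is.na(alleleCalls(x)$a))   # brute-force recount
  for (k in c(0L, 4L, 7L)) {
    y <- filterByScoredLoci(x, k)
    expect_equal(nInd(y), sum(scored >= k))
    expect_true(all(indInfo(y)$id %in% indInfo(x)$id))
  }
  expect_equal(nInd(filterByScoredLoci(x, 0L)), nInd(x))
  y4 <- filterByScoredLoci(x, 4L)
  expect_equal(indInfo(filterByScoredLoci(y4, 4L))$id, indInfo(y4)$id)  # idempotent
  # site metadata survives even if a site empties out
  expect_equal(siteInfo(y4), siteInfo(x))
})

test_that("allele frequencies count copies and flag empty cells", {
  x <- mkCell(list(c(1, 1), c(1, 2)))
  ft <- alleleFrequencies(x)
  expect_equal(unname(ftFrequencies(ft, 1)[, 1]), c(0.75, 0.25))
  expect_equal(unname(ftSampleSizes(ft)[1, 1]), 2L)

  blank <- mkCell(list(c(NA, NA), c(NA, NA)))
  ftb <- alleleFrequencies(blank)
  expect_false(ftb@available[1, 1])
  expect_error(heterozygosity(ftb), "unavailable")

  sim <- simulateGenotypes(simConfig(nPops = 3, nPerPop = 25, nLoci = 5,
                                     allelesPerLocus = 6, F = 0.1, seed = 8))
  ftS <- alleleFrequencies(sim$dataset)
  for (l in seq_len(5)) {
    f <- ftFrequencies(ftS, l)
    expect_true(all(abs(colSums(f) - 1) < 1e-12))
    # independent tally for one population
    cal <- alleleCalls(sim$dataset)
    p1 <- popLabels(sim$dataset) == "site1"
    pool <- c(cal$a[p1, l], cal$b[p1, l]); pool <- pool[!is.na(pool)]
    tab <- table(factor(pool, levels = rownames(f)))
    expect_equal(unname(f[, "site1"]), unname(as.numeric(tab) / length(pool)))
  }
})
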
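test_that("chord distance matches closed forms and hand evaluation", {
  # identical frequency vectors -> 0
  x <- mkData(matrix(c(1L, 2L, 1L, 2L)), matrix(c(1L, 2L, 1L, 2L)),
              c("pA", "pA", "pB", "pB"))
  ft <- alleleFrequencies(x)
  expect_equal(chordDistance(ft, "pA", "pB"), 0)

  # disjoint allele sets at a single locus -> (2/pi) sqrt(2)
  y <- mkData(matrix(c(1L, 2L)), matrix(c(1L, 2L)), c("pA", "pB"))
  expect_equal(chordDistance(alleleFrequencies(y), "pA", "pB"),
               2 / pi * sqrt(2), tolerance = 1e-12)

  # p = (.5,.5) vs q = (1,0): d = (2/pi) sqrt(2 (1 - sqrt(.5))) ~ 0.4870
  z <- mkData(matrix(c(1L, 1L)), matrix(c(2L, 1L)), c("pA", "pB"))
  expect_equal(chordDistance(alleleFrequencies(z), "pA", "pB"),
               2 / pi * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-12)
  expect_lt(abs(chordDistance(alleleFrequencies(z), "pA", "pB") - 0.4870), 5e-4)
})

test_that("chord matrices are symmetric, bounded and null-aware only when nulls exist", {
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 25, nLoci = 5,
                                     allelesPerLocus = 8, F = 0.05, seed = 41))
  x <- sim$dataset
  m <- dcMatrix(x, ina = FALSE)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m <= 2 / pi * sqrt(2) + 1e-12))

  # with r = 0 estimated everywhere the INA and raw matrices are identical
  raw <- alleleFrequencies(x)
  cft <- correctedFrequencies(x)
  cft@nullFreq[] <- 0
  cft@freqs <- raw@freqs
  pops <- unique(popLabels(x))
  expect_equal(chordDistance(cft, pops[1], pops[2], ina = TRUE),
               chordDistance(raw, pops[1], pops[2], ina = FALSE),
               tolerance = 1e-12)
  # and on clean data the estimated nulls are in fact near zero
  expect_lt(mean(nullAlleleTable(x)), 0.05)

  # allele relabelling leaves D_C unchanged
  cal <- alleleCalls(x)
  y <- mkData(cal$a + 100L, cal$b + 100L, popLabels(x))
  expect_equal(dcMatrix(y, ina = FALSE), m, tolerance = 1e-12)
})

test_that("leave-one-locus-out comparison equals brute-force recomputation", {
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 25, nLoci = 6,
                                     allelesPerLocus = 8, F = 0.08, seed = 43))
  x <- sim$dataset
  full <- dcMatrix(x, ina = FALSE)
  self <- deltaDc(full, full)
  expect_equal(self$r, 1)
  expect_equal(self$meanDelta, 0)

  # drop locus 6 by rebuilding the dataset without it
  cal <- alleleCalls(x)
  x5 <- mkData(cal$a[, 1:5], cal$b[, 1:5], popLabels(x))
  m5 <- dcMatrix(x5, ina = FALSE)
  cmp <- deltaDc(full, m5)
  # brute force: per-pair mean over 6 loci vs mean over 5 loci
  ft <- alleleFrequencies(x)
  pops <- unique(popLabels(x))
  prs <- combn(pops, 2)
  deltas <- vapply(seq_len(ncol(prs)), function(i) {
    d6 <- chordDistance(ft, prs[1, i], prs[2, i])
    perLoc <- vapply(1:6, function(l) {
      f <- ftFrequencies(ft, l)
      2 / pi * sqrt(2 * max(1 - sum(sqrt(f[, prs[1, i]] * f[, prs[2, i]])), 0))
    }, numeric(1))
    abs(d6 - mean(perLoc[1:5]))
  }, numeric(1))
  expect_equal(cmp$meanDelta, mean(deltas), tolerance = 1e-12)
  expect_equal(nrow(prs) * ncol(prs) / 2, 6)   # 4 populations -> 6 pairs
})

test_that("great-circle distances follow the haversine closed forms", {
  s0 <- data.frame(site_id = c("a", "b"), latitude = c(10, 10),
                   longitude = c(20, 20))
  expect_equal(greatCircleMatrix(s0)["a", "b"], 0)

  anti <- data.frame(site_id = c("a", "b"), latitude = c(0, 0),
                     longitude = c(0, 180))
  expect_equal(greatCircleMatrix(anti)["a", "b"], pi * 6371.0088,
               tolerance = 1e-6)

  # two southern New Zealand coastal sites ~ 63 km apart as the crow flies;
  # marine-route distances exceed great-circle, so only a weak bound is safe
  nz <- data.frame(site_id = c("s1", "s2"),
                   latitude = -c(46 + 22.890 / 60, 45 + 54.858 / 60),
                   longitude = c(169 + 47.017 / 60, 170 + 29.317 / 60))
  d <- greatCircleMatrix(nz)["s1", "s2"]
  expect_gt(d, 40); expect_lt(d, 372)
})

test_that("gap matrices encode the habitat partition", {
  m <- gapMatrix(c("s1", "s2", "s3", "s4"), c("s1", "s2", "s3"), "s4")
  expect_equal(sum(m[upper.tri(m)]), 3)
  expect_equal(m["s1", "s4"], 1)
  expect_equal(m["s1", "s2"], 0)

  all0 <- gapMatrix(c("s1", "s2"), c("s1", "s2"), character(0))
  expect_true(all(all0 == 0))

  # a x b ones for a partition into groups of size a and b
  m2 <- gapMatrix(paste0("s", 1:5), paste0("s", 1:2), paste0("s", 3:5))
  expect_equal(sum(m2[upper.tri(m2)]), 2 * 3)
  expect_error(gapMatrix(c("s1", "s2"), "s1", c("s1", "s2")), "partition")
})
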
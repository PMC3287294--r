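fixedDiffData <- function(n = 50) {
  # two populations fixed for different alleles at one locus
  mkData(matrix(c(rep(1L, n), rep(2L, n))),
         matrix(c(rep(1L, n), rep(2L, n))),
         rep(c("pA", "pB"), each = n))
}

test_that("gene diversities reach their closed-form limits", {
  ft <- alleleFrequencies(fixedDiffData(400))
  H <- heterozygosity(ft)
  expect_equal(H$Hs, 0, tolerance = 1e-12)
  expect_equal(H$Ht, 0.5, tolerance = 2e-3)     # finite-n correction term

  # identical allele frequencies everywhere -> H_S ~ H_T
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 200, nLoci = 3,
                                     allelesPerLocus = 8, F = 0, seed = 2))
  H2 <- heterozygosity(alleleFrequencies(sim$dataset))
  expect_equal(H2$Hs, H2$Ht, tolerance = 0.01)
})

test_that("gene diversities match a direct-summation oracle", {
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 30, nLoci = 5,
                                     allelesPerLocus = 10, F = 0.05,
                                     nullFreq = 0.1, blankFailureRate = 0.05,
                                     seed = 31))
  ft <- alleleFrequencies(sim$dataset)
  H <- heterozygosity(ft)
  # independent recomputation, plain loops over the same frequency table
  hsAll <- htAll <- numeric(5)
  for (l in 1:5) {
    f <- ftFrequencies(ft, l); n <- ftSampleSizes(ft)[, l]
    k <- ncol(f)
    nt <- k / sum(1 / n)
    hs <- nt / (nt - 1) * (1 - sum(apply(f, 2, function(v) sum(v^2))) / k)
    pb <- apply(f, 1, mean)
    htAll[l] <- 1 - sum(pb^2) + hs / (k * nt)
    hsAll[l] <- hs
  }
  expect_equal(H$Hs, mean(hsAll), tolerance = 1e-12)
  expect_equal(H$Ht, mean(htAll), tolerance = 1e-12)
})

test_that("Jost's D hits its closed-form extremes and CIs cover the point", {
  d1 <- jostD(fixedDiffData(60), c("pA", "pB"), nBoot = 100, seed = 3)
  expect_equal(unname(d1$perLocus[1]), 1, tolerance = 1e-12)
  expect_equal(d1$D, 1, tolerance = 1e-12)

  # two independent samples from one population (identical true frequencies)
  sim <- simulateGenotypes(simConfig(nPops = 2, nPerPop = 200, nLoci = 4,
                                     allelesPerLocus = 8, F = 0, seed = 4))
  d0 <- jostD(sim$dataset, unique(popLabels(sim$dataset)), nBoot = 100, seed = 3)
  expect_lt(abs(d0$D), 0.05)

  for (d in list(d1, d0)) {
    expect_lte(d$ci[1], d$D)
    expect_gte(d$ci[2], d$D)
  }
})

test_that("Weir-Cockerham theta behaves at the fixation and panmixia limits", {
  expect_gt(weirFst(fixedDiffData(50), c("pA", "pB"))$theta, 0.9)

  sim <- simulateGenotypes(simConfig(nPops = 1, nPerPop = 50, nLoci = 4,
                                     allelesPerLocus = 8, seed = 6))
  cal <- alleleCalls(sim$dataset)
  dup <- mkData(rbind(cal$a, cal$a), rbind(cal$b, cal$b),
                rep(c("pA", "pB"), each = 50))
  expect_lt(abs(weirFst(dup, c("pA", "pB"))$theta), 0.02)
})

test_that("theta matches an independent variance-component transcription", {
  # straight re-transcription of the 1984 per-allele components, kept
  # deliberately separate from the implementation
  oracleTheta <- function(x, pops) {
    cal <- alleleCalls(x)
    num <- den <- 0
    for (l in seq_len(nLoci(x))) {
      ns <- ps <- hs <- list()
      for (i in seq_along(pops)) {
        idx <- popLabels(x) == pops[i]
        a <- cal$a[idx, l]; b <- cal$b[idx, l]
        keep <- !is.na(a); a <- a[keep]; b <- b[keep]
        ns[[i]] <- length(a)
        uni <- x@markers[[l]]
        ps[[i]] <- (tabulate(match(a, uni), length(uni)) +
                    tabulate(match(b, uni), length(uni))) / (2 * length(a))
        hcar <- a[a != b]
        hs[[i]] <- (tabulate(match(hcar, uni), length(uni)) +
                    tabulate(match(b[a != b], uni), length(uni))) / length(a)
      }
      r <- length(pops); n <- unlist(ns)
      nbar <- mean(n); nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
      for (al in seq_along(x@markers[[l]])) {
        p <- vapply(ps, `[`, 0, al); h <- vapply(hs, `[`, 0, al)
        pbar <- sum(n * p) / (r * nbar)
        s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(n * h) / (r * nbar)
        a1 <- nbar / nc * (s2 - 1 / (nbar - 1) *
              (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
        b1 <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
              (2 * nbar - 1) / (4 * nbar) * hbar)
        c1 <- hbar / 2
        num <- num + a1; den <- den + a1 + b1 + c1
      }
    }
    num / den
  }
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 25, nLoci = 4,
                                     allelesPerLocus = 7, F = 0.05, seed = 17))
  pops <- unique(popLabels(sim$dataset))
  expect_equal(weirFst(sim$dataset, pops)$theta,
               oracleTheta(sim$dataset, pops), tolerance = 1e-12)
})

test_that("null-corrected theta is less biased than raw theta under null alleles", {
  errs <- vapply(1:20, function(s) {
    sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 50, nLoci = 7,
                                       allelesPerLocus = 10, F = 0.05,
                                       nullFreq = 0.2, seed = 9000 + s))
    pops <- unique(popLabels(sim$dataset))
    c(raw = abs(weirFst(sim$dataset, pops)$theta - 0.05),
      ena = abs(weirFst(sim$dataset, pops, useEna = TRUE)$theta - 0.05))
  }, numeric(2))
  expect_lt(mean(errs["ena", ]), mean(errs["raw", ]))
})

test_that("standardized G''_ST worked values and closed forms hold", {
  expect_lt(abs(gDoublePrimeSt(0.749, 0.732, 4) - 0.113), 0.002)
  expect_lt(abs(gDoublePrimeSt(0.755, 0.737, 4) - 0.118), 0.002)
  expect_equal(gDoublePrimeSt(0.5, 0, 2), 1)            # fixed differences
  expect_equal(gDoublePrimeSt(0.6, 0.6, 3), 0)          # no differentiation
  expect_equal(gDoublePrimeSt(0, 0, 2), 0)              # no diversity
  # monotone increasing in H_T at fixed H_S and k
  g <- vapply(seq(0.5, 0.9, 0.1), gDoublePrimeSt, 0, Hs = 0.4, k = 4)
  expect_true(all(diff(g) > 0))
})

test_that("migrant numbers follow the island-model transform with an Inf sentinel", {
  expect_equal(round(migrantsNm(0.113, 0.011), 1), 20.2)
  expect_equal(round(migrantsNm(0.118, 0.007), 1), 31.5)
  expect_identical(migrantsNm(0.5, 0), Inf)
  expect_identical(migrantsNm(0.5, -0.01), Inf)
})

test_that("the pairwise report covers all scopes and is order/relabel invariant", {
  sim <- simulateGenotypes(simConfig(nPops = 4, nPerPop = 20, nLoci = 4,
                                     allelesPerLocus = 6, F = 0.05,
                                     nullFreq = 0.1, seed = 23))
  x <- sim$dataset
  rep1 <- pairwiseReport(x, nBoot = 50, seed = 99)
  expect_equal(nrow(rep1), 7L)                       # 1 global + choose(4,2)
  expect_equal(rep1$scope[1], "global")
  expect_equal(rep1$k, c(4L, rep(2L, 6)))

  # shuffling individuals must not change any statistic at a fixed seed
  set.seed(1); perm <- sample(nInd(x))
  rep2 <- pairwiseReport(x[perm], populations = unique(popLabels(x)),
                         nBoot = 50, seed = 99)
  expect_equal(rep2, rep1, tolerance = 1e-12)

  # relabelling alleles must not change D or G''_ST
  cal <- alleleCalls(x)
  shift <- function(m) m + 40L
  y <- mkData(shift(cal$a), shift(cal$b), popLabels(x))
  dx <- jostD(x, unique(popLabels(x)), nBoot = 10, seed = 1)
  dy <- jostD(y, unique(popLabels(y)), nBoot = 10, seed = 1)
  expect_equal(dy$D, dx$D, tolerance = 1e-12)
})
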
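test_that("homozygote-excess p matches the exact re-pairing distribution", {
  # alleles {1,1,2,2}: of the 3 distinct pairings, only (11)(22) has 2
  # homozygous pairs, so P(hom >= 2) = 1/3 under the permutation null
  x <- mkCell(list(c(1, 1), c(2, 2)))
  hw <- hweTest(x, "p1", 1, nPerm = 6000, seed = 42)
  expect_equal(hw$observedHom, 2)
  expect_lt(abs(hw$pExcess - 1 / 3), 0.025)
  expect_lt(hw$pExcess, 0.5)

  mono <- mkCell(list(c(1, 1), c(1, 1)))
  expect_equal(hweTest(mono, "p1", 1, nPerm = 100, seed = 1)$pExcess, 1)
})

test_that("EM estimate agrees with a brute-force likelihood grid search", {
  # apparent counts: het(1,2)=32, hom(1)=34, hom(2)=34, no blanks,
  # likelihood conditioned on non-blank outcomes
  fit <- estimateNullEM(
    mkCell(c(replicate(32, c(1, 2), simplify = FALSE),
             replicate(34, c(1, 1), simplify = FALSE),
             replicate(34, c(2, 2), simplify = FALSE))),
    "p1", 1, blankMode = "blanks-excluded")
  expect_true(fit@converged)
  # independent oracle: grid over (p1, r) of the observed-data likelihood
  ll <- function(p1, r) {
    p2 <- pmax(1 - r - p1, 1e-300)
    out <- 32 * log(2 * p1 * p2) + 34 * log(p1^2 + 2 * p1 * r) +
      34 * log(p2^2 + 2 * p2 * r) - 100 * log(1 - r^2)
    out[1 - r - p1 <= 0 | p1 <= 0] <- -Inf
    out
  }
  g <- expand.grid(p1 = seq(0.01, 0.98, 1e-3), r = seq(0, 0.5, 1e-3))
  best <- g[which.max(ll(g$p1, g$r)), ]
  expect_lt(abs(fit@r - best$r), 1.5e-3)
  expect_equal(fit@r, 0.2195, tolerance = 1e-3)   # frozen from the grid oracle
  expect_equal(fit@r + sum(fit@visibleFreqs), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and the estimate is relabel-invariant", {
  for (s in 1:5) {
    x <- drawNullCell(n = 120, nAlleles = 6, r = 0.2, seed = 100 + s)
    for (mode in c("blanks-as-nulls", "blanks-excluded")) {
      est <- estimateNullEM(x, "p1", 1, blankMode = mode)
      expect_true(all(diff(est@logLik) > -1e-8))
    }
    # relabelling visible alleles must not change r
    cal <- alleleCalls(x)
    relab <- setNames(sample(1000:1100, 10), 100 + 2 * (1:10))
    a2 <- matrix(relab[as.character(cal$a[, 1])]); b2 <- matrix(relab[as.character(cal$b[, 1])])
    y <- mkData(a2, b2, rep("p1", nInd(x)))
    expect_equal(estimateNullEM(y, "p1", 1)@r, estimateNullEM(x, "p1", 1)@r,
                 tolerance = 1e-9)
  }
})

test_that("exact HWE counts without blanks give a zero null estimate", {
  # n = 32 at p = 1/2: 16 hets, 8 + 8 homozygotes, exactly HWE proportions
  x <- mkCell(c(replicate(16, c(1, 2), simplify = FALSE),
                replicate(8, c(1, 1), simplify = FALSE),
                replicate(8, c(2, 2), simplify = FALSE)))
  for (mode in c("blanks-as-nulls", "blanks-excluded"))
    expect_lt(estimateNullEM(x, "p1", 1, blankMode = mode)@r, 1e-6)
})

test_that("EM recovers a known null-allele frequency from large samples", {
  err <- vapply(1:10, function(s)
    abs(estimateNullEM(drawNullCell(500, 10, 0.2, seed = 7000 + s), "p1", 1)@r - 0.2),
    numeric(1))
  expect_lt(mean(err), 0.03)
})

test_that("artifact diagnosis separates null alleles from large-allele dropout", {
  nullVerdicts <- vapply(1:20, function(s) {
    x <- drawNullCell(100, 8, 0.25, seed = 300 + s)
    diagnoseArtifact(x, "p1", 1, nPerm = 300, seed = s)$verdict
  }, character(1))
  expect_gte(mean(nullVerdicts == "consistent-with-null-alleles"), 0.7)

  dropVerdicts <- vapply(1:20, function(s) {
    set.seed(400 + s)
    lab <- 100 + 2 * (1:8)
    a <- sample(lab, 120, replace = TRUE); b <- sample(lab, 120, replace = TRUE)
    # convert size-distant heterozygotes to large-allele homozygotes
    d <- abs(a - b)
    hit <- d >= quantile(d[d > 0], 0.75) & runif(120) < 0.8
    big <- pmax(a, b)
    a[hit] <- big[hit]; b[hit] <- big[hit]
    x <- mkData(matrix(a), matrix(b), rep("p1", 120))
    diagnoseArtifact(x, "p1", 1, nPerm = 300, seed = s)$verdict
  }, character(1))
  drops <- dropVerdicts[dropVerdicts != "no-excess"]
  expect_gt(length(drops), 10)
  expect_gte(mean(drops == "consistent-with-dropout"), 0.7)

  hweVerdicts <- vapply(1:20, function(s) {
    x <- drawNullCell(80, 8, 0, seed = 500 + s)
    diagnoseArtifact(x, "p1", 1, nPerm = 300, seed = s)$verdict
  }, character(1))
  expect_gte(mean(hweVerdicts == "no-excess"), 0.8)
})

test_that("null-frequency summaries reduce to the expected arithmetic", {
  m <- matrix(c(0.1, 0.0, 0.2, 0.2), 2, 2,
              dimnames = list(c("pA", "pB"), c("L1", "L2")))
  s <- summarizeNullFrequencies(m)
  expect_equal(s$perPopulation$mean, c(0.15, 0.1))
  expect_equal(s$perPopulation$sd[2], sd(c(0, 0.2)))
  expect_equal(s$perLocus$min, c(0, 0.2))
  expect_equal(s$perLocus$max, c(0.1, 0.2))
  single <- summarizeNullFrequencies(matrix(0.1, 1, 1, dimnames = list("p", "L")))
  expect_equal(single$perPopulation$sd, 0)
})
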
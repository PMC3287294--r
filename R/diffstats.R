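# Subset an AlleleFreqTable to a set of populations (cells are independent,
# so this is pure column selection).
subsetFreqTable <- function(ft, pops) {
  stopifnot(all(pops %in% ftPops(ft)))
  new("AlleleFreqTable",
      freqs = lapply(ft@freqs, function(f) f[, pops, drop = FALSE]),
      n = ft@n[pops, , drop = FALSE],
      available = ft@available[pops, , drop = FALSE],
      corrected = ft@corrected,
      nullFreq = ft@nullFreq[pops, , drop = FALSE])
}

# Per-locus bias-corrected gene diversities from a frequency matrix
# (alleles x populations) and per-population scored sample sizes.
# H_S = (ntilde/(ntilde-1)) * (1 - mean_k sum_a p_ka^2)
# H_T = 1 - sum_a pbar_a^2 + H_S/(k*ntilde),  pbar = across-population mean
hsHtLocus <- function(f, n) {
  k <- ncol(f)
  ntilde <- k / sum(1 / n)
  meanHomo <- mean(colSums(f^2))
  hs <- (ntilde / (ntilde - 1)) * (1 - meanHomo)
  pbar <- rowMeans(f)
  ht <- 1 - sum(pbar^2) + hs / (k * ntilde)
  c(hs = hs, ht = ht, ntilde = ntilde)
}

#' Within-population and total gene diversity (H_S, H_T)
#'
#' Per-locus bias-corrected expected heterozygosities with harmonic-mean
#' sample sizes, averaged arithmetically over loci. Whether the values are
#' raw or null-corrected follows from the frequency table supplied (see
#' \code{\link{alleleFrequencies}} / \code{\link{correctedFrequencies}}).
#'
#' @param ft an \linkS4class{AlleleFreqTable}; every cell must be available
#' @return list with \code{Hs}, \code{Ht} (over-loci means), \code{k},
#'   and a \code{perLocus} data.frame (\code{hs}, \code{ht}, \code{ntilde})
#' @export
heterozygosity <- function(ft) {
  if (!all(ft@available)) {
    bad <- which(!ft@available, arr.ind = TRUE)[1L, ]
    stop(sprintf("frequency cell unavailable: population %s, locus %s",
                 ftPops(ft)[bad[1L]], ftLoci(ft)[bad[2L]]))
  }
  per <- t(vapply(seq_along(ft@freqs), function(l)
    hsHtLocus(ft@freqs[[l]], ft@n[, l]), numeric(3)))
  per <- as.data.frame(per)
  rownames(per) <- ftLoci(ft)
  list(Hs = mean(per$hs), Ht = mean(per$ht), k = nrow(ft@n), perLocus = per)
}

# D for one locus from allele-count matrices: counts alleles x pops, n scored.
jostDLocus <- function(f, n) {
  v <- hsHtLocus(f, n)
  if (v["hs"] >= 1 - 1e-12) return(NA_real_)
  k <- ncol(f)
  unname((v["ht"] - v["hs"]) / (1 - v["hs"]) * k / (k - 1))
}

#' Jost's D with HWE-conditional bootstrap confidence interval
#'
#' Per-locus D = [(H_T - H_S)/(1 - H_S)] * k/(k-1) from raw (uncorrected)
#' frequencies with the bias-corrected gene diversities, averaged over loci.
#' The 95% CI comes from \code{nBoot} resamplings in which, per locus, allele
#' copies are resampled within populations when every involved population
#' passes the homozygote-excess test at that locus (alpha), and whole
#' genotypes otherwise.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param populations site ids to contrast (>= 2)
#' @param nBoot bootstrap resamplings
#' @param seed RNG seed
#' @param alpha HWE-test level deciding the per-locus resampling unit
#' @param hwePerm permutations for the per-locus HWE screen
#' @return list with \code{D} (mean over loci), \code{ci} (percentile 2.5/97.5),
#'   \code{perLocus}, \code{resampleUnit} per locus
#' @export
jostD <- function(x, populations, nBoot = 1000L, seed = NULL,
                  alpha = 0.05, hwePerm = 200L) {
  stopifnot(length(populations) >= 2L)
  loci <- markerNames(x)
  cells <- lapply(loci, function(l)
    lapply(populations, function(p) cellCalls(x, p, l)))
  universe <- lapply(seq_along(loci), function(l) as.character(x@markers[[l]]))

  countsFromCalls <- function(a, b, uni)
    as.numeric(table(factor(as.character(c(a, b)), levels = uni)))

  freqMat <- function(cellList, uni) {
    f <- vapply(cellList, function(cc) {
      cnt <- countsFromCalls(cc$a, cc$b, uni)
      cnt / (2 * cc$n)
    }, numeric(length(uni)))
    matrix(f, nrow = length(uni))
  }

  perLocus <- vapply(seq_along(loci), function(l) {
    jostDLocus(freqMat(cells[[l]], universe[[l]]),
               vapply(cells[[l]], `[[`, 0, "n"))
  }, numeric(1))
  if (any(is.na(perLocus)))
    warning("locus with H_S = 1 skipped (D undefined): ",
            paste(loci[is.na(perLocus)], collapse = ", "))

  unit <- vapply(seq_along(loci), function(l) {
    ps <- vapply(populations, function(p)
      hweTest(x, p, l, nPerm = hwePerm, seed = deriveSeed(seed, l * 131L + match(p, populations)))$pExcess,
      numeric(1))
    if (all(ps >= alpha)) "allele" else "genotype"
  }, character(1))

  boots <- withSeed(deriveSeed(seed, 999983L), {
    vapply(seq_len(nBoot), function(bi) {
      dl <- vapply(seq_along(loci), function(l) {
        uni <- universe[[l]]
        res <- lapply(cells[[l]], function(cc) {
          if (cc$n == 0L) return(cc)
          if (unit[l] == "allele") {
            pool <- c(cc$a, cc$b)
            s <- sample(pool, length(pool), replace = TRUE)
            list(a = s[seq_len(cc$n)], b = s[cc$n + seq_len(cc$n)], n = cc$n)
          } else {
            idx <- sample.int(cc$n, cc$n, replace = TRUE)
            list(a = cc$a[idx], b = cc$b[idx], n = cc$n)
          }
        })
        jostDLocus(freqMat(res, uni), vapply(res, `[[`, 0, "n"))
      }, numeric(1))
      mean(dl, na.rm = TRUE)
    }, numeric(1))
  })
  point <- mean(perLocus, na.rm = TRUE)
  # recentred percentile CI: within-population resampling inflates
  # differentiation slightly, so raw percentiles can exclude the point
  # estimate; recentring on the bootstrap mean removes that bias
  list(D = point,
       ci = point + quantile(boots - mean(boots), c(0.025, 0.975), names = FALSE),
       perLocus = setNames(perLocus, loci),
       resampleUnit = setNames(unit, loci))
}

# Weir-Cockerham variance components for one locus.
#   p: alleles x pops frequency matrix; h: alleles x pops observed (or
#   HWE-expected) frequency of heterozygotes carrying each allele; n: scored
#   sample sizes. Returns c(a, abc) summed over alleles.
wcComponentsLocus <- function(p, h, n) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  aSum <- abcSum <- 0
  for (A in seq_len(nrow(p))) {
    pA <- p[A, ]; hA <- h[A, ]
    pbar <- sum(n * pA) / (r * nbar)
    s2 <- sum(n * (pA - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * hA) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    aSum <- aSum + a
    abcSum <- abcSum + a + b + cc
  }
  c(a = aSum, abc = abcSum)
}

#' Weir-Cockerham F_ST (theta), raw or null-corrected (ENA)
#'
#' Multiallelic theta from among-population (a), among-individual (b) and
#' within-individual (c) variance components, combined as a ratio of sums
#' over alleles and loci. With \code{useEna = TRUE} the components are built
#' from EM-corrected visible-allele frequencies (null class excluded, visible
#' frequencies renormalized) and HWE-expected heterozygosities, because
#' null-corrected individual genotypes do not exist; this is the standard
#' "excluding null alleles" approximation.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param populations site ids (>= 2)
#' @param useEna use null-corrected frequencies
#' @param blankMode blank handling for the EM when \code{useEna}
#' @param corrFt optional pre-computed corrected \linkS4class{AlleleFreqTable}
#'   (avoids re-running the EM)
#' @param nBoot bootstrap-over-loci replicates for a 95% CI (0 = skip)
#' @param seed RNG seed for the bootstrap
#' @return list with \code{theta}, \code{ci} (or NULL), \code{perLocus}
#'   components
#' @export
weirFst <- function(x, populations, useEna = FALSE,
                    blankMode = "blanks-as-nulls", corrFt = NULL,
                    nBoot = 0L, seed = NULL) {
  stopifnot(length(populations) >= 2L)
  loci <- markerNames(x)
  if (useEna && is.null(corrFt))
    corrFt <- correctedFrequencies(x, populations, blankMode)
  comp <- matrix(NA_real_, length(loci), 2L,
                 dimnames = list(loci, c("a", "abc")))
  for (l in seq_along(loci)) {
    ns <- vapply(populations, function(p) cellCalls(x, p, l)$n, 0L)
    if (any(ns < 2L)) next
    if (useEna) {
      p <- ftFrequencies(corrFt, l)[, populations, drop = FALSE]
      h <- 2 * p * (1 - p)
    } else {
      uni <- as.character(x@markers[[l]])
      p <- matrix(0, length(uni), length(populations),
                  dimnames = list(uni, populations))
      h <- p
      for (pi in seq_along(populations)) {
        cc <- cellCalls(x, populations[pi], l)
        cnt <- table(factor(as.character(c(cc$a, cc$b)), levels = uni))
        p[, pi] <- as.numeric(cnt) / (2 * cc$n)
        het <- cc$a != cc$b
        if (any(het)) {
          hcnt <- table(factor(as.character(c(cc$a[het], cc$b[het])), levels = uni))
          h[, pi] <- as.numeric(hcnt) / cc$n
        }
      }
    }
    comp[l, ] <- wcComponentsLocus(p, h, ns)
  }
  ok <- !is.na(comp[, 1L])
  if (!any(ok))
    stop("no locus with >= 2 scored individuals in every population")
  theta <- sum(comp[ok, "a"]) / sum(comp[ok, "abc"])
  ci <- NULL
  if (nBoot > 0L) {
    idx <- which(ok)
    ci <- withSeed(deriveSeed(seed, 424243L), {
      reps <- vapply(seq_len(nBoot), function(b) {
        s <- sample(idx, length(idx), replace = TRUE)
        sum(comp[s, "a"]) / sum(comp[s, "abc"])
      }, numeric(1))
      quantile(reps, c(0.025, 0.975), names = FALSE)
    })
  }
  list(theta = theta, ci = ci, perLocus = comp)
}

#' Hedrick's standardized G''_ST
#'
#' G''_ST = k (H_T - H_S) / [(k H_T - H_S)(1 - H_S)], with H_T and H_S the
#' over-loci averaged total and mean within-population gene diversities and k
#' the number of sampled populations (k = 4 for global, k = 2 for pairwise
#' contrasts in the study design this reproduces).
#'
#' @param Ht,Hs over-loci averaged total and within-population gene diversity
#' @param k number of populations (>= 2)
#' @return the scalar G''_ST; 0 when H_T = 0 (no diversity, no
#'   differentiation)
#' @export
gDoublePrimeSt <- function(Ht, Hs, k) {
  stopifnot(k >= 2, Hs >= 0, Ht <= 1, Hs < 1)
  if (Ht == 0) return(0)
  k * (Ht - Hs) / ((k * Ht - Hs) * (1 - Hs))
}

#' Island-model migrant number N_m = (1 - G''_ST) / (4 F_ST)
#'
#' @param gppSt standardized differentiation G''_ST
#' @param fst F_ST estimate (conventionally the null-corrected one)
#' @return migrants per generation; \code{Inf} when F_ST <= 0 (indefinite)
#' @export
migrantsNm <- function(gppSt, fst) {
  if (fst <= 0) return(Inf)
  (1 - gppSt) / (4 * fst)
}

#' Global and population-pairwise differentiation report
#'
#' For the global scope (all k populations) and each of the k(k-1)/2 pairs:
#' null-corrected H_S/H_T, Jost's D with HWE-conditional bootstrap CI (raw
#' frequencies), Weir-Cockerham F_ST raw and ENA-corrected with over-loci
#' bootstrap CIs, G''_ST from the corrected diversities (k = 2 for pairs,
#' k = n populations globally), and N_m = (1 - G''_ST)/(4 F_ST(ENA)).
#'
#' @param x a \linkS4class{GenotypeData}
#' @param populations site ids (default: all sites with individuals)
#' @param nBoot bootstrap replicates for D and F_ST CIs
#' @param seed RNG seed
#' @param blankMode blank handling for the null-allele EM
#' @return data.frame, one row per scope ("global" first, then "a|b" pairs)
#' @export
pairwiseReport <- function(x, populations = NULL, nBoot = 1000L, seed = NULL,
                           blankMode = "blanks-as-nulls") {
  if (is.null(populations)) populations <- unique(popLabels(x))
  corrFt <- correctedFrequencies(x, populations, blankMode)
  scopes <- c(list(populations),
              if (length(populations) >= 2L)
                combn(populations, 2L, simplify = FALSE))
  rows <- lapply(seq_along(scopes), function(si) {
    pops <- scopes[[si]]
    scope <- if (si == 1L) "global" else paste(pops, collapse = "|")
    H <- heterozygosity(subsetFreqTable(corrFt, pops))
    D <- jostD(x, pops, nBoot = nBoot, seed = deriveSeed(seed, si * 7L))
    fRaw <- weirFst(x, pops, useEna = FALSE, nBoot = nBoot,
                    seed = deriveSeed(seed, si * 7L + 1L))
    fEna <- weirFst(x, pops, useEna = TRUE, corrFt = subsetFreqTable(corrFt, pops),
                    nBoot = nBoot, seed = deriveSeed(seed, si * 7L + 2L))
    g <- gDoublePrimeSt(H$Ht, H$Hs, length(pops))
    data.frame(scope = scope, k = length(pops),
               Hs = H$Hs, Ht = H$Ht,
               Dest = D$D, Dest_lo = D$ci[1L], Dest_hi = D$ci[2L],
               Fst = fRaw$theta, Fst_lo = fRaw$ci[1L], Fst_hi = fRaw$ci[2L],
               FstENA = fEna$theta, FstENA_lo = fEna$ci[1L], FstENA_hi = fEna$ci[2L],
               GppSt = g, Nm = migrantsNm(g, fEna$theta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
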
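#' Monte-Carlo test for homozygote excess (Hardy-Weinberg diagnostic)
#'
#' Pools the 2n observed allele copies in one population x locus cell and
#' re-pairs them at random \code{nPerm} times; the statistic is the number of
#' homozygous pairs, and the one-tailed p-value for homozygote excess carries
#' a +1 pseudo-count so p is never zero:
#' p = (1 + #\{permuted >= observed\}) / (1 + nPerm).
#'
#' @param x a \linkS4class{GenotypeData}
#' @param population site id
#' @param locus locus name or index
#' @param nPerm number of random re-pairings
#' @param seed RNG seed (optional)
#' @return list with \code{observedHom}, \code{pExcess}, \code{nPerm},
#'   \code{n} (scored individuals)
#' @export
hweTest <- function(x, population, locus, nPerm = 1000L, seed = NULL) {
  cc <- cellCalls(x, population, locus)
  if (cc$n < 2L) stop("hweTest needs >= 2 scored individuals in the cell")
  pool <- c(cc$a, cc$b)
  obs <- sum(cc$a == cc$b)
  if (length(unique(pool)) == 1L) {
    return(list(observedHom = obs, pExcess = 1, nPerm = as.integer(nPerm), n = cc$n))
  }
  withSeed(seed, {
    ge <- 0L
    m <- length(pool)
    for (i in seq_len(nPerm)) {
      s <- sample(pool)
      if (sum(s[seq(1L, m, 2L)] == s[seq(2L, m, 2L)]) >= obs) ge <- ge + 1L
    }
    list(observedHom = obs, pExcess = (1 + ge) / (1 + nPerm),
         nPerm = as.integer(nPerm), n = cc$n)
  })
}

# EM core on summary counts for one cell.
#   hetA, hetB: allele labels of apparent heterozygotes (character)
#   hom: named counts of apparent homozygotes per allele
#   nBlank: number of fully blank individuals
nullEMCore <- function(hetA, hetB, homCounts, nBlank,
                       blankMode = c("blanks-as-nulls", "blanks-excluded"),
                       tol = 1e-8, maxIter = 10000L) {
  blankMode <- match.arg(blankMode)
  alleles <- sort(unique(c(hetA, hetB, names(homCounts)[homCounts > 0])))
  nHet <- length(hetA)
  h <- setNames(numeric(length(alleles)), alleles)
  h[names(homCounts)] <- homCounts
  # allele copies carried by heterozygotes (observed without ambiguity)
  e <- setNames(numeric(length(alleles)), alleles)
  te <- table(factor(c(hetA, hetB), levels = alleles))
  e[] <- as.numeric(te)
  nGeno <- nHet + sum(h)
  if (blankMode == "blanks-excluded") nBlank0 <- 0 else nBlank0 <- nBlank

  # no apparent homozygotes and no (counted) blanks -> no information, r = 0
  if (sum(h) == 0 && nBlank0 == 0) {
    p <- e / sum(e)
    return(list(r = 0, p = p, iterations = 0L, converged = TRUE,
                logLik = sum(e * log(p)) + nHet * log(2)))
  }

  loglik <- function(p, r) {
    ll <- 0
    if (nHet > 0) ll <- ll + sum(e * log(pmax(p, 1e-300))) + nHet * log(2)
    hi <- h > 0
    if (any(hi)) ll <- ll + sum(h[hi] * log(pmax(p[hi]^2 + 2 * p[hi] * r, 1e-300)))
    if (blankMode == "blanks-as-nulls") {
      if (nBlank > 0) ll <- ll + nBlank * 2 * log(max(r, 1e-300))
    } else {
      ll <- ll - nGeno * log(max(1 - r^2, 1e-300))
    }
    ll
  }

  # init: naive visible frequencies scaled by a small starting null frequency
  obsCopies <- e + 2 * h
  r <- if (nBlank0 + sum(h) > 0) 0.05 else 0
  p <- obsCopies / sum(obsCopies) * (1 - r)
  llTrace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    llTrace <- c(llTrace, loglik(p, r))
    # E-step
    denom <- p + 2 * r
    Eii <- ifelse(denom > 0, h * p / denom, 0)
    Einu <- h - Eii
    if (blankMode == "blanks-as-nulls") {
      mBlank <- nBlank
      N <- nGeno + nBlank
    } else {
      mBlank <- if (r > 0) nGeno * r^2 / (1 - r^2) else 0
      N <- nGeno + mBlank
    }
    # M-step: expected allele-copy counts
    copies <- e + 2 * Eii + Einu
    nuCopies <- sum(Einu) + 2 * mBlank
    tot <- 2 * N
    pNew <- copies / tot
    rNew <- nuCopies / tot
    delta <- max(abs(c(pNew - p, rNew - r)))
    p <- pNew; r <- rNew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  llTrace <- c(llTrace, loglik(p, r))
  # boundary polish: EM converges sublinearly when the MLE sits at r = 0, so
  # a tiny residual r can survive the stopping rule; snap to the boundary
  # when it does not cost likelihood
  if (r > 0 && r < 1e-3 && (blankMode == "blanks-excluded" || nBlank == 0)) {
    p0 <- p / sum(p)
    if (loglik(p0, 0) >= llTrace[length(llTrace)] - 1e-9) {
      p <- p0; r <- 0
      llTrace <- c(llTrace, loglik(p0, 0))
    }
  }
  list(r = r, p = p, iterations = it, converged = converged, logLik = llTrace)
}

#' EM estimate of the null-allele frequency in one population x locus cell
#'
#' Maximum-likelihood estimation under Hardy-Weinberg equilibrium with a
#' hidden null allele: true genotype classes occur with probabilities
#' p_i^2, 2 p_i p_j, 2 p_i r and r^2; a true heterozygote (i,j) is observed as
#' such, true (i,i) and (i,null) both appear as apparent homozygote i, and
#' (null,null) yields a blank. \code{blankMode = "blanks-as-nulls"} counts
#' blank loci as the (null,null) class; \code{"blanks-excluded"} conditions
#' the likelihood on a non-blank outcome.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param population site id
#' @param locus locus name or index
#' @param blankMode how blank genotypes enter the likelihood
#' @param tol EM convergence tolerance on the maximum absolute frequency
#'   change per iteration
#' @param maxIter iteration cap
#' @return a \linkS4class{NullAlleleEstimate}
#' @export
estimateNullEM <- function(x, population, locus,
                           blankMode = c("blanks-as-nulls", "blanks-excluded"),
                           tol = 1e-8, maxIter = 10000L) {
  blankMode <- match.arg(blankMode)
  cc <- cellCalls(x, population, locus)
  locusName <- if (is.character(locus)) locus else markerNames(x)[locus]
  het <- cc$a != cc$b
  hetA <- as.character(cc$a[het]); hetB <- as.character(cc$b[het])
  homTab <- table(as.character(cc$a[!het]))
  homCounts <- setNames(as.numeric(homTab), names(homTab))
  if (cc$n == 0L && cc$nBlank == 0L)
    stop(sprintf("cell %s / %s has no individuals", population, locusName))
  fit <- nullEMCore(hetA, hetB, homCounts, cc$nBlank, blankMode, tol, maxIter)
  new("NullAlleleEstimate",
      population = as.character(population), locus = locusName,
      r = fit$r, visibleFreqs = fit$p, nIterations = as.integer(fit$iterations),
      converged = fit$converged, blankMode = blankMode, logLik = fit$logLik)
}

#' Null-allele frequency matrix over all cells
#'
#' Runs \code{\link{estimateNullEM}} for every population x locus cell.
#' Monomorphic or empty cells get r = 0.
#'
#' @inheritParams estimateNullEM
#' @param populations site ids (default all)
#' @return populations x loci numeric matrix of estimated null frequencies
#' @export
nullAlleleTable <- function(x, populations = NULL,
                            blankMode = c("blanks-as-nulls", "blanks-excluded"),
                            tol = 1e-8, maxIter = 10000L) {
  blankMode <- match.arg(blankMode)
  if (is.null(populations)) populations <- unique(popLabels(x))
  loci <- markerNames(x)
  out <- matrix(0, length(populations), length(loci),
                dimnames = list(populations, loci))
  for (p in populations) for (l in loci) {
    cc <- cellCalls(x, p, l)
    if (cc$n == 0L) next
    est <- estimateNullEM(x, p, l, blankMode, tol, maxIter)
    out[p, l] <- est@r
  }
  out
}

#' Null-corrected allele frequency table
#'
#' EM-corrects every cell and returns visible-allele frequencies renormalized
#' to sum to 1 (the "excluding null alleles" convention used for F_ST and
#' heterozygosity); the per-cell null frequencies are retained in the
#' \code{nullFreq} slot so that null-inclusive statistics (chord distance
#' with INA) can re-augment them.
#'
#' @inheritParams nullAlleleTable
#' @return an \linkS4class{AlleleFreqTable} with \code{corrected = TRUE}
#' @export
correctedFrequencies <- function(x, populations = NULL,
                                 blankMode = c("blanks-as-nulls", "blanks-excluded"),
                                 tol = 1e-8, maxIter = 10000L) {
  blankMode <- match.arg(blankMode)
  if (is.null(populations)) populations <- unique(popLabels(x))
  raw <- alleleFrequencies(x, populations)
  loci <- markerNames(x)
  nullF <- raw@nullFreq
  freqs <- raw@freqs
  for (li in seq_along(loci)) {
    for (p in populations) {
      if (!raw@available[p, li]) next
      est <- estimateNullEM(x, p, li, blankMode, tol, maxIter)
      nullF[p, li] <- est@r
      f <- freqs[[li]][, p]
      f[] <- 0
      vis <- est@visibleFreqs
      tot <- sum(vis)
      if (tot > 0) f[names(vis)] <- vis / tot  # renormalize visible classes
      else f[] <- freqs[[li]][, p]             # degenerate: keep raw
      freqs[[li]][, p] <- f
    }
  }
  new("AlleleFreqTable", freqs = freqs, n = raw@n, available = raw@available,
      corrected = TRUE, nullFreq = nullF)
}

#' Classify a homozygote excess as null-allele-like or dropout-like
#'
#' A simplified stand-in for a full scoring-artifact diagnostic battery: if
#' the cell shows no significant homozygote excess (Monte-Carlo p >= alpha)
#' the verdict is \code{"no-excess"}. Otherwise the heterozygote deficit
#' (expected minus observed heterozygote count per unordered allele pair,
#' expectations from observed allele frequencies) is partitioned by quartiles
#' of the allele-size difference of the expected heterozygote classes: a
#' deficit concentrated (more than half of the total) in the largest
#' size-difference quartile is \code{"consistent-with-dropout"} (large-allele
#' dropout removes size-distant heterozygotes preferentially), otherwise
#' \code{"consistent-with-null-alleles"}. With fewer than 4 distinct size
#' differences the dropout test is skipped and a significant excess defaults
#' to the null-allele verdict.
#'
#' @inheritParams hweTest
#' @param alpha significance level for the excess test
#' @param nPerm permutations for the excess test
#' @return list with \code{verdict}, \code{pExcess}, \code{topQuartileShare}
#' @export
diagnoseArtifact <- function(x, population, locus, alpha = 0.05,
                             nPerm = 1000L, seed = NULL) {
  hw <- hweTest(x, population, locus, nPerm = nPerm, seed = seed)
  if (hw$pExcess >= alpha)
    return(list(verdict = "no-excess", pExcess = hw$pExcess,
                topQuartileShare = NA_real_))
  cc <- cellCalls(x, population, locus)
  pool <- c(cc$a, cc$b)
  alleles <- sort(unique(pool))
  freq <- as.numeric(table(factor(pool, levels = alleles))) / length(pool)
  if (length(alleles) < 2L)
    return(list(verdict = "consistent-with-null-alleles", pExcess = hw$pExcess,
                topQuartileShare = NA_real_))
  prs <- combn(seq_along(alleles), 2L)
  sizeDiff <- abs(alleles[prs[1L, ]] - alleles[prs[2L, ]])
  expHet <- 2 * freq[prs[1L, ]] * freq[prs[2L, ]] * cc$n
  obsHet <- numeric(ncol(prs))
  het <- cc$a != cc$b
  if (any(het)) {
    key <- paste(pmin(cc$a[het], cc$b[het]), pmax(cc$a[het], cc$b[het]))
    keyAll <- paste(alleles[prs[1L, ]], alleles[prs[2L, ]])
    tb <- table(key)
    obsHet[match(names(tb), keyAll)] <- as.numeric(tb)
  }
  deficit <- expHet - obsHet
  if (length(unique(sizeDiff)) < 4L)
    return(list(verdict = "consistent-with-null-alleles", pExcess = hw$pExcess,
                topQuartileShare = NA_real_))
  q3 <- quantile(rep(sizeDiff, times = pmax(round(expHet * 100), 1L)), 0.75,
                 names = FALSE, type = 1)
  top <- sizeDiff >= q3
  totalDef <- sum(deficit)
  share <- if (totalDef > 0) sum(deficit[top]) / totalDef else NA_real_
  verdict <- if (!is.na(share) && share > 0.5) "consistent-with-dropout"
             else "consistent-with-null-alleles"
  list(verdict = verdict, pExcess = hw$pExcess, topQuartileShare = share)
}

#' Summaries of null-allele frequencies in table form
#'
#' @param rmat populations x loci matrix of estimated null frequencies (as
#'   returned by \code{\link{nullAlleleTable}})
#' @return list with \code{perPopulation} (mean and sample SD over loci) and
#'   \code{perLocus} (min and max over populations)
#' @export
summarizeNullFrequencies <- function(rmat) {
  perPop <- data.frame(
    population = rownames(rmat),
    mean = apply(rmat, 1, mean),
    sd = apply(rmat, 1, function(v) if (length(v) > 1L) sd(v) else 0),
    row.names = NULL, stringsAsFactors = FALSE)
  perLocus <- data.frame(
    locus = colnames(rmat),
    min = apply(rmat, 2, min),
    max = apply(rmat, 2, max),
    row.names = NULL, stringsAsFactors = FALSE)
  list(perPopulation = perPop, perLocus = perLocus)
}
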
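mantelR <- function(mGen, mX) {
  a <- upperTri(mGen); b <- upperTri(mX)
  if (var(a) == 0 || var(b) == 0)
    stop("Mantel r undefined: a matrix has zero variance in its off-diagonal entries")
  cor(a, b)
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices; the null distribution is built by simultaneous random
#' row-and-column permutation of the predictor matrix \code{mX}. One-sided
#' p-value with a +1 pseudo-count: p = (1 + #\{r_perm >= r_obs\})/(1 + nPerm)
#' for \code{alternative = "greater"} (and the mirror for \code{"less"}).
#'
#' @param mGen,mX conformable symmetric matrices sharing labels (n >= 3)
#' @param nPerm number of permutations
#' @param seed RNG seed
#' @param alternative direction of the test
#' @return a \linkS4class{MantelResult}
#' @export
mantelTest <- function(mGen, mX, nPerm = 30000L, seed = NULL,
                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  mGen <- checkSquareLabelled(mGen, "mGen"); mX <- checkSquareLabelled(mX, "mX")
  n <- nrow(mGen)
  stopifnot(n >= 3L, all(dim(mGen) == dim(mX)))
  rObs <- mantelR(mGen, mX)
  cnt <- withSeed(seed, {
    s <- 0L
    for (i in seq_len(nPerm)) {
      pm <- sample.int(n)
      rp <- mantelR(mGen, mX[pm, pm])
      if ((alternative == "greater" && rp >= rObs) ||
          (alternative == "less" && rp <= rObs)) s <- s + 1L
    }
    s
  })
  new("MantelResult", r = rObs, p = (1 + cnt) / (1 + nPerm),
      nPerm = as.integer(nPerm), alternative = alternative,
      controlledFor = "")
}

partialR <- function(rxy, rxz, ryz) {
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 0)
    stop("partial correlation undefined: a control correlation is +/-1")
  (rxy - rxz * ryz) / sqrt(den)
}

#' Partial Mantel permutation test
#'
#' Partial Pearson correlation of upper triangles,
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)), between
#' \code{mGen} and \code{mX} controlling for \code{mZ}. The null permutes the
#' predictor \code{mX} (rows and columns together) and recomputes the partial
#' correlation. One-sided p as in \code{\link{mantelTest}}.
#'
#' @inheritParams mantelTest
#' @param mZ control matrix
#' @param controlLabel label recorded in the result
#' @return a \linkS4class{MantelResult}
#' @export
partialMantelTest <- function(mGen, mX, mZ, nPerm = 30000L, seed = NULL,
                              alternative = c("greater", "less"),
                              controlLabel = "Z") {
  alternative <- match.arg(alternative)
  mGen <- checkSquareLabelled(mGen, "mGen")
  mX <- checkSquareLabelled(mX, "mX"); mZ <- checkSquareLabelled(mZ, "mZ")
  n <- nrow(mGen)
  stopifnot(n >= 3L, all(dim(mGen) == dim(mX)), all(dim(mGen) == dim(mZ)))
  ryz <- mantelR(mGen, mZ)
  rObs <- partialR(mantelR(mGen, mX), mantelR(mX, mZ), ryz)
  cnt <- withSeed(seed, {
    s <- 0L
    for (i in seq_len(nPerm)) {
      pm <- sample.int(n)
      mp <- mX[pm, pm]
      rp <- partialR(mantelR(mGen, mp), mantelR(mp, mZ), ryz)
      if ((alternative == "greater" && rp >= rObs) ||
          (alternative == "less" && rp <= rObs)) s <- s + 1L
    }
    s
  })
  new("MantelResult", r = rObs, p = (1 + cnt) / (1 + nPerm),
      nPerm = as.integer(nPerm), alternative = alternative,
      controlledFor = controlLabel)
}

# Mean distance between same-allele instance pairs at one locus, given the
# alleles x sites count matrix C and the site distance matrix D: pair weight
# between sites s,t is sum_a C[a,s] C[a,t] (s < t) and choose(C[a,s], 2)
# within sites (distance 0).
sashaLocusOM <- function(C, D) {
  M <- crossprod(C)           # sites x sites: sum_a C[a,s] C[a,t]
  cross <- sum(upperTri(M * D))
  nCross <- sum(upperTri(M))
  nWithin <- sum(C * (C - 1) / 2)
  pairs <- nCross + nWithin
  list(sum = cross, pairs = pairs)
}

#' Spatial analysis of shared alleles (SAShA)
#'
#' Each allele copy is an instance located at its carrier's sampling site.
#' OM is the mean geographic distance over all unordered pairs of instances
#' sharing allele identity, pooled across alleles and loci; EM is the mean
#' distance over all instance pairs at a locus regardless of identity,
#' combined over loci with the same pooling weights (each locus's same-allele
#' pair count). Under panmixia OM = EM. The permutation null shuffles allele
#' identities across instances within each locus (site slots fixed) and the
#' two-sided p-value is
#' p = (1 + #\{|OM_perm - EM| >= |OM_obs - EM|\})/(1 + nPerm).
#'
#' @param x a \linkS4class{GenotypeData}; every individual must map to a
#'   georeferenced site unless \code{geoMatrix} is supplied
#' @param geoMatrix site-by-site distance matrix in km (default: great-circle
#'   distances from the site coordinates); within-site distance is 0
#' @param nPerm number of permutations
#' @param seed RNG seed
#' @return a \linkS4class{SashaResult}
#' @export
sasha <- function(x, geoMatrix = NULL, nPerm = 10000L, seed = NULL) {
  sites <- x@sites
  if (is.null(geoMatrix)) {
    if (any(is.na(sites$latitude)))
      stop("sites lack coordinates; supply geoMatrix")
    geoMatrix <- greatCircleMatrix(sites)
  }
  usedSites <- intersect(rownames(geoMatrix), unique(popLabels(x)))
  D <- geoMatrix[usedSites, usedSites, drop = FALSE]
  loci <- markerNames(x)
  siteOf <- match(popLabels(x), usedSites)

  instances <- lapply(seq_along(loci), function(l) {
    a <- x@alleleA[, l]; b <- x@alleleB[, l]
    keep <- !is.na(a)
    allele <- c(a[keep], b[keep]); site <- c(siteOf[keep], siteOf[keep])
    o <- order(site, allele)  # canonical order: permutation stream does not
    list(allele = allele[o], site = site[o])  # depend on individual order
  })

  nSites <- length(usedSites)
  countMatrix <- function(alleleIdx, nAlleles, site) {
    matrix(tabulate((site - 1L) * nAlleles + alleleIdx, nbins = nAlleles * nSites),
           nAlleles, nSites)
  }

  instances <- lapply(instances, function(ins) {
    u <- sort(unique(ins$allele))
    ins$alleleIdx <- match(ins$allele, u)
    ins$nAlleles <- length(u)
    ins
  })

  perLocus <- lapply(seq_along(loci), function(l) {
    ins <- instances[[l]]
    if (!length(ins$allele)) return(NULL)
    C <- countMatrix(ins$alleleIdx, ins$nAlleles, ins$site)
    om <- sashaLocusOM(C, D)
    tot <- matrix(colSums(C), nrow = 1L)
    em <- sashaLocusOM(tot, D)   # all pairs regardless of identity
    list(locus = loci[l], omSum = om$sum, omPairs = om$pairs,
         emMean = if (em$pairs > 0) em$sum / em$pairs else NA_real_)
  })
  perLocus <- Filter(Negate(is.null), perLocus)
  w <- vapply(perLocus, `[[`, numeric(1), "omPairs")
  if (any(w == 0))
    warning("locus with only singleton alleles skipped: ",
            paste(vapply(perLocus[w == 0], `[[`, character(1), "locus"),
                  collapse = ", "))
  keep <- w > 0
  perLocus <- perLocus[keep]; w <- w[keep]
  if (!length(perLocus)) stop("no locus contributes same-allele pairs")
  omSum <- vapply(perLocus, `[[`, numeric(1), "omSum")
  emMean <- vapply(perLocus, `[[`, numeric(1), "emMean")
  OM <- sum(omSum) / sum(w)
  EM <- sum(w * emMean) / sum(w)

  keptLoci <- vapply(perLocus, `[[`, character(1), "locus")
  obsDev <- abs(OM - EM)
  cnt <- withSeed(seed, {
    s <- 0L
    for (i in seq_len(nPerm)) {
      tot <- 0
      for (li in seq_along(keptLoci)) {
        ins <- instances[[match(keptLoci[li], loci)]]
        C <- countMatrix(sample(ins$alleleIdx), ins$nAlleles, ins$site)
        tot <- tot + sashaLocusOM(C, D)$sum
      }
      if (abs(tot / sum(w) - EM) >= obsDev) s <- s + 1L
    }
    s
  })
  new("SashaResult", OM = OM, EM = EM, p = (1 + cnt) / (1 + nPerm),
      nPerm = as.integer(nPerm),
      perLocus = data.frame(locus = keptLoci, OM = omSum / w, EM = emMean,
                            pairs = w, stringsAsFactors = FALSE))
}

#' Correlation of two matched distance matrices with a t-distribution p-value
#'
#' Plain Pearson correlation between the upper triangles of two conformable
#' matrices (e.g., two species' chord-distance matrices over the same sites)
#' with the usual two-tailed t-test on n - 2 degrees of freedom. Note the
#' entries are pairwise distances, not independent observations, so the
#' p-value is descriptive rather than exact.
#'
#' @param mA,mB conformable labelled symmetric matrices
#' @return list with \code{r}, \code{p}, \code{df}
#' @export
dcCorrelation <- function(mA, mB) {
  a <- upperTri(mA); b <- upperTri(mB)
  n <- length(a)
  r <- cor(a, b)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), df = n - 2)
}
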
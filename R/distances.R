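# Frequency vectors for one locus and two populations on the union of their
# allele states, optionally augmented with the null class (INA).
chordVectors <- function(ft, locus, popA, popB, ina) {
  f <- ftFrequencies(ft, locus)
  p <- f[, popA]; q <- f[, popB]
  if (ina) {
    if (!ft@corrected)
      stop("ina = TRUE needs a null-corrected frequency table")
    rA <- ftNullFreq(ft)[popA, locus]; rB <- ftNullFreq(ft)[popB, locus]
    p <- c(p * (1 - rA), null = rA)
    q <- c(q * (1 - rB), null = rB)
  }
  list(p = p, q = q)
}

#' Cavalli-Sforza & Edwards chord distance between two populations
#'
#' Per locus d = (2/pi) * sqrt(2 * (1 - sum_a sqrt(p_a q_a))), averaged over
#' loci. With \code{ina = TRUE} ("including null alleles") each frequency
#' vector is the EM-corrected visible vector augmented by its null class, so
#' the null allele participates as one shared allelic state. Allele label
#' universes are unioned automatically (the frequency table already carries
#' the full per-marker universe).
#'
#' @param ft an \linkS4class{AlleleFreqTable} (null-corrected when
#'   \code{ina = TRUE})
#' @param popA,popB population labels
#' @param ina include the null-allele class
#' @return the over-loci mean chord distance
#' @export
chordDistance <- function(ft, popA, popB, ina = FALSE) {
  d <- vapply(seq_along(ft@freqs), function(l) {
    v <- chordVectors(ft, l, popA, popB, ina)
    s <- sum(sqrt(v$p * v$q))
    (2 / pi) * sqrt(2 * max(1 - s, 0))
  }, numeric(1))
  mean(d)
}

#' Chord-distance matrix over all population pairs
#'
#' @param x a \linkS4class{GenotypeData}
#' @param ina null-aware variant (default TRUE, the study's convention)
#' @param populations site ids (default all)
#' @param blankMode blank handling for the EM (when \code{ina})
#' @param ft optional pre-computed frequency table
#' @return symmetric labelled matrix of D_C values
#' @export
dcMatrix <- function(x, ina = TRUE, populations = NULL,
                     blankMode = "blanks-as-nulls", ft = NULL) {
  if (is.null(populations)) populations <- unique(popLabels(x))
  if (is.null(ft))
    ft <- if (ina) correctedFrequencies(x, populations, blankMode)
          else alleleFrequencies(x, populations)
  m <- matrix(0, length(populations), length(populations),
              dimnames = list(populations, populations))
  for (i in seq_along(populations)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- chordDistance(ft, populations[i], populations[j], ina)
  }
  m
}

#' Compare two distance matrices (leave-one-locus-out diagnostic)
#'
#' Pearson correlation between the vectorized upper triangles, plus the mean
#' and SD of the absolute entry-wise differences.
#'
#' @param mA,mB conformable labelled symmetric matrices
#' @return list with \code{r}, \code{meanDelta}, \code{sdDelta}
#' @export
deltaDc <- function(mA, mB) {
  if (!all(dim(mA) == dim(mB)))
    stop("distance matrices have different dimensions")
  a <- upperTri(mA); b <- upperTri(mB)
  list(r = cor(a, b), meanDelta = mean(abs(a - b)), sdDelta = sd(abs(a - b)))
}

#' Great-circle (haversine) distance matrix between sites, in km
#'
#' A stand-in for externally measured route distances (coastal studies often
#' use shortest marine routes, which are an input, not something this
#' function can reproduce): haversine distances on a sphere of radius
#' 6371.0088 km.
#'
#' @param sites data.frame with \code{site_id}, \code{latitude},
#'   \code{longitude}
#' @return symmetric labelled matrix (km)
#' @export
greatCircleMatrix <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    d <- geosphere::distHaversine(
      c(sites$longitude[i], sites$latitude[i]),
      c(sites$longitude[j], sites$latitude[j]), r = 6371008.8) / 1000
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Binary habitat-discontinuity (gap) indicator matrix
#'
#' @param sites data.frame with a \code{site_id} column, or a character vector
#'   of site ids
#' @param groupA,groupB site ids on either side of the discontinuity; the two
#'   groups must partition the sites
#' @return symmetric 0/1 matrix: 1 iff the pair spans the partition
#' @export
gapMatrix <- function(sites, groupA, groupB) {
  ids <- if (is.data.frame(sites)) sites$site_id else as.character(sites)
  if (!setequal(c(groupA, groupB), ids) || length(intersect(groupA, groupB)))
    stop("groupA and groupB must partition the site ids")
  side <- ifelse(ids %in% groupA, 0L, 1L)
  m <- abs(outer(side, side, `-`))
  dimnames(m) <- list(ids, ids)
  m
}
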
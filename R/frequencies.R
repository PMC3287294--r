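# Internal: allele calls for one population x locus cell, blanks dropped.
# Genotypes are returned in canonical (a, b) order so that seeded resampling
# downstream is invariant to the order individuals appear in the dataset.
cellCalls <- function(x, pop, locus) {
  idx <- which(popLabels(x) == pop)
  a <- x@alleleA[idx, locus]; b <- x@alleleB[idx, locus]
  keep <- !is.na(a)
  a <- a[keep]; b <- b[keep]
  o <- order(a, b)
  list(a = a[o], b = b[o], n = length(a), nBlank = sum(!keep))
}

#' Observed allele frequencies per population and locus
#'
#' Tabulates allele-copy counts over scored individuals in each population x
#' locus cell and divides by 2n. Cells with no scored genotypes are flagged
#' unavailable; downstream statistics must skip them or fail loudly.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param populations which populations (site ids) to include; default all
#'   sites with at least one individual
#' @return an \linkS4class{AlleleFreqTable} (raw, uncorrected)
#' @export
alleleFrequencies <- function(x, populations = NULL) {
  if (is.null(populations)) populations <- unique(popLabels(x))
  loci <- markerNames(x)
  nmat <- matrix(0L, length(populations), length(loci),
                 dimnames = list(populations, loci))
  avail <- matrix(FALSE, length(populations), length(loci),
                  dimnames = list(populations, loci))
  freqs <- vector("list", length(loci)); names(freqs) <- loci
  for (l in seq_along(loci)) {
    uni <- as.character(x@markers[[l]])
    f <- matrix(0, length(uni), length(populations),
                dimnames = list(uni, populations))
    for (p in seq_along(populations)) {
      cc <- cellCalls(x, populations[p], l)
      nmat[p, l] <- cc$n
      if (cc$n >= 1L) {
        avail[p, l] <- TRUE
        tab <- table(factor(as.character(c(cc$a, cc$b)), levels = uni))
        f[, p] <- as.numeric(tab) / (2 * cc$n)
      }
    }
    freqs[[l]] <- f
  }
  new("AlleleFreqTable", freqs = freqs, n = nmat, available = avail,
      corrected = FALSE, nullFreq = nmat * 0)
}
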
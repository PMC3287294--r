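#' @title Core data containers
#' @description S4 classes holding codominant multiallelic genotype data and
#'   derived allele-frequency tables.
#' @name raftgen-classes
NULL

HABITATS <- c("rock", "kelp-holdfast", "kelp-surface", "unknown")

#' Codominant multiallelic genotype dataset
#'
#' Holds apparent genotypes (two allele calls per locus, both present or both
#' missing) for a set of individuals sampled from georeferenced sites, plus
#' per-marker allele universes. Sampling site doubles as the population unit.
#'
#' @slot alleleA,alleleB integer matrices (individuals x loci) of allele
#'   labels (fragment sizes in base pairs); \code{NA} in both = blank locus.
#'   Pairs are stored unordered with \code{alleleA <= alleleB}.
#' @slot individuals data.frame with columns \code{id}, \code{site_id},
#'   \code{habitat} (one of rock, kelp-holdfast, kelp-surface, unknown) and
#'   \code{species} (assigned label or \code{NA}).
#' @slot markers named list, one integer vector of allele labels per locus.
#' @slot sites data.frame with columns \code{site_id}, \code{latitude},
#'   \code{longitude}.
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    individuals = "data.frame",
    markers = "list",
    sites = "data.frame"
  )
)

setValidity("GenotypeData", function(object) {
  a <- object@alleleA; b <- object@alleleB
  msgs <- character()
  if (!all(dim(a) == dim(b))) msgs <- c(msgs, "alleleA/alleleB dimensions differ")
  if (nrow(a) != nrow(object@individuals))
    msgs <- c(msgs, "individual table does not match genotype matrix rows")
  if (ncol(a) != length(object@markers))
    msgs <- c(msgs, "marker list does not match genotype matrix columns")
  if (any(is.na(a) != is.na(b)))
    msgs <- c(msgs, "half-missing genotypes present (one allele called)")
  if (!all(is.na(a) | is.na(b) | a <= b))
    msgs <- c(msgs, "allele pairs not stored in sorted order")
  ind <- object@individuals
  need <- c("id", "site_id", "habitat", "species")
  if (!all(need %in% names(ind)))
    msgs <- c(msgs, "individuals must have columns id, site_id, habitat, species")
  else {
    if (anyDuplicated(ind$id)) msgs <- c(msgs, "duplicate individual ids")
    if (!all(ind$habitat %in% HABITATS))
      msgs <- c(msgs, sprintf("habitat labels outside {%s}", paste(HABITATS, collapse = ", ")))
    if (!all(ind$site_id %in% object@sites$site_id))
      msgs <- c(msgs, "individual site_id does not resolve to a known site")
  }
  st <- object@sites
  if (!all(c("site_id", "latitude", "longitude") %in% names(st)))
    msgs <- c(msgs, "sites must have columns site_id, latitude, longitude")
  else {
    if (any(st$latitude < -90 | st$latitude > 90, na.rm = TRUE))
      msgs <- c(msgs, "latitude outside [-90, 90]")
    if (any(st$longitude < -180 | st$longitude > 180, na.rm = TRUE))
      msgs <- c(msgs, "longitude outside [-180, 180]")
  }
  for (l in seq_along(object@markers)) {
    uni <- object@markers[[l]]
    if (length(uni) < 1L || anyDuplicated(uni)) {
      msgs <- c(msgs, sprintf("marker %d: allele labels must be unique and non-empty", l))
      next
    }
    seen <- c(a[, l], b[, l])
    if (!all(seen[!is.na(seen)] %in% uni))
      msgs <- c(msgs, sprintf("marker %d: genotype calls outside the marker allele set", l))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeData object
#'
#' @param alleleA,alleleB integer matrices (individuals x loci); \code{NA} in
#'   both matrices marks a blank locus. The pair is reordered internally so
#'   genotypes are unordered.
#' @param individuals data.frame with columns \code{id}, \code{site_id},
#'   \code{habitat}; a \code{species} column is added if absent.
#' @param sites data.frame with \code{site_id}, \code{latitude}, \code{longitude}.
#' @param markers optional named list of allele-label vectors; defaults to the
#'   sorted observed alleles per locus.
#' @return a \linkS4class{GenotypeData} object
#' @export
GenotypeData <- function(alleleA, alleleB, individuals, sites, markers = NULL) {
  alleleA <- as.matrix(alleleA); alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"; storage.mode(alleleB) <- "integer"
  if (any(is.na(alleleA) != is.na(alleleB)))
    stop("half-missing genotypes are malformed: a locus is either fully called or blank")
  lo <- pmin(alleleA, alleleB); hi <- pmax(alleleA, alleleB)
  alleleA <- lo; alleleB <- hi
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (is.null(individuals$species)) individuals$species <- NA_character_
  individuals$id <- as.character(individuals$id)
  individuals$site_id <- as.character(individuals$site_id)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$site_id <- as.character(sites$site_id)
  if (is.null(markers)) {
    markers <- lapply(seq_len(ncol(alleleA)), function(l) {
      u <- sort(unique(c(alleleA[, l], alleleB[, l])))
      u <- u[!is.na(u)]
      if (!length(u)) u <- 0L  # placeholder universe for an all-blank locus
      as.integer(u)
    })
    names(markers) <- colnames(alleleA)
  }
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    names(markers) <- paste0("L", seq_along(markers))
  dimnames(alleleA) <- dimnames(alleleB) <- list(individuals$id, names(markers))
  rownames(individuals) <- NULL
  rownames(sites) <- NULL
  new("GenotypeData", alleleA = alleleA, alleleB = alleleB,
      individuals = individuals, markers = markers, sites = sites)
}

#' @describeIn GenotypeData number of individuals
#' @param x a GenotypeData object
#' @export
nInd <- function(x) nrow(x@alleleA)

#' @describeIn GenotypeData number of loci
#' @export
nLoci <- function(x) ncol(x@alleleA)

#' @describeIn GenotypeData marker (locus) names
#' @export
markerNames <- function(x) names(x@markers)

#' @describeIn GenotypeData individual metadata table
#' @export
indInfo <- function(x) x@individuals

#' @describeIn GenotypeData site metadata table
#' @export
siteInfo <- function(x) x@sites

#' @describeIn GenotypeData population (= sampling site) label per individual
#' @export
popLabels <- function(x) x@individuals$site_id

#' @describeIn GenotypeData raw allele-call matrices as a list(a=, b=)
#' @export
alleleCalls <- function(x) list(a = x@alleleA, b = x@alleleB)

#' @describeIn GenotypeData count of non-missing loci per individual
#' @export
scoredLoci <- function(x) rowSums(!is.na(x@alleleA))

#' Subset a GenotypeData by individual index
#' @param x GenotypeData
#' @param i integer or logical index over individuals
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  new("GenotypeData",
      alleleA = x@alleleA[i, , drop = FALSE],
      alleleB = x@alleleB[i, , drop = FALSE],
      individuals = x@individuals[i, , drop = FALSE],
      markers = x@markers,
      sites = x@sites)
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nInd(object), "individuals x", nLoci(object), "loci\n")
  cat("  sites:", paste(object@sites$site_id, collapse = ", "), "\n")
  miss <- mean(is.na(object@alleleA))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  sp <- object@individuals$species
  if (any(!is.na(sp))) {
    tb <- table(sp, useNA = "no")
    cat("  species labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' Per-population, per-locus allele frequency table
#'
#' @slot freqs list (one element per locus) of allele x population matrices of
#'   visible-allele frequencies; each available column sums to 1.
#' @slot n populations x loci matrix of scored individual counts.
#' @slot available logical populations x loci matrix; FALSE marks cells with
#'   no scored genotypes.
#' @slot corrected logical; TRUE when frequencies are EM null-corrected
#'   (visible classes renormalized to sum 1).
#' @slot nullFreq populations x loci matrix of estimated null-allele
#'   frequencies (all zero when \code{corrected} is FALSE).
#' @exportClass AlleleFreqTable
setClass("AlleleFreqTable",
  representation(
    freqs = "list",
    n = "matrix",
    available = "matrix",
    corrected = "logical",
    nullFreq = "matrix"
  )
)

setValidity("AlleleFreqTable", function(object) {
  msgs <- character()
  for (l in seq_along(object@freqs)) {
    f <- object@freqs[[l]]
    ok <- object@available[, l]
    if (any(ok)) {
      s <- colSums(f[, ok, drop = FALSE])
      if (any(abs(s - 1) > 1e-9))
        msgs <- c(msgs, sprintf("locus %d: available frequency columns must sum to 1", l))
    }
  }
  if (any(object@nullFreq < 0 | object@nullFreq >= 1, na.rm = TRUE))
    msgs <- c(msgs, "null-allele frequencies must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", nrow(object@n), "populations x", ncol(object@n), "loci",
      if (object@corrected) "(null-corrected)" else "(raw)", "\n")
  cat("  populations:", paste(rownames(object@n), collapse = ", "), "\n")
  if (object@corrected)
    cat(sprintf("  mean null-allele frequency: %.3f\n", mean(object@nullFreq)))
})

#' @describeIn AlleleFreqTable population labels
#' @param x an AlleleFreqTable
#' @export
ftPops <- function(x) rownames(x@n)

#' @describeIn AlleleFreqTable locus names
#' @export
ftLoci <- function(x) colnames(x@n)

#' @describeIn AlleleFreqTable scored-sample-size matrix (populations x loci)
#' @export
ftSampleSizes <- function(x) x@n

#' @describeIn AlleleFreqTable frequency matrix (alleles x populations) for one locus
#' @param locus locus name or index
#' @export
ftFrequencies <- function(x, locus) x@freqs[[locus]]

#' @describeIn AlleleFreqTable null-allele frequency matrix (populations x loci)
#' @export
ftNullFreq <- function(x) x@nullFreq

#' EM null-allele estimate for one population x locus cell
#'
#' @slot population,locus cell identifiers.
#' @slot r estimated null-allele frequency.
#' @slot visibleFreqs named numeric; corrected visible-allele frequencies
#'   summing to 1 - r.
#' @slot nIterations,converged EM bookkeeping.
#' @slot blankMode "blanks-as-nulls" or "blanks-excluded".
#' @slot logLik observed-data log-likelihood trace (one entry per iteration).
#' @exportClass NullAlleleEstimate
setClass("NullAlleleEstimate",
  representation(
    population = "character", locus = "character",
    r = "numeric", visibleFreqs = "numeric",
    nIterations = "integer", converged = "logical",
    blankMode = "character", logLik = "numeric"
  )
)

setValidity("NullAlleleEstimate", function(object) {
  if (object@r < 0) return("r must be >= 0")
  if (abs(object@r + sum(object@visibleFreqs) - 1) > 1e-9)
    return("r + sum(visibleFreqs) must equal 1")
  TRUE
})

setMethod("show", "NullAlleleEstimate", function(object) {
  cat(sprintf("NullAlleleEstimate [%s / %s]: r = %.4f (%s, %d EM iterations%s)\n",
              object@population, object@locus, object@r, object@blankMode,
              object@nIterations,
              if (object@converged) "" else ", NOT converged"))
})

#' No-admixture cluster assignment result
#'
#' @slot Q individuals x K matrix of posterior membership proportions
#'   (chain-averaged, label-aligned).
#' @slot chainQ list of per-chain Q matrices.
#' @slot assigned character vector: cluster label or "AMBIGUOUS".
#' @slot threshold Q-value threshold used by \code{\link{assignSpecies}} (NA
#'   until assignment is applied).
#' @slot converged logical; FALSE when inter-chain Q correlation fell below
#'   the convergence criterion.
#' @slot minChainCor minimum pairwise Pearson correlation between chain Q's.
#' @exportClass AssignmentResult
setClass("AssignmentResult",
  representation(
    Q = "matrix", chainQ = "list", assigned = "character",
    threshold = "numeric", converged = "logical", minChainCor = "numeric"
  )
)

setMethod("show", "AssignmentResult", function(object) {
  K <- ncol(object@Q)
  cat(sprintf("AssignmentResult: %d individuals, K = %d, %d chain(s)\n",
              nrow(object@Q), K, length(object@chainQ)))
  cat(sprintf("  min inter-chain Q correlation: %.4f%s\n", object@minChainCor,
              if (object@converged) "" else "  [convergence warning]"))
  if (length(object@assigned)) {
    tb <- table(object@assigned)
    cat("  assignments:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' Mantel / partial Mantel test result
#'
#' @slot r matrix correlation (partial when \code{controlledFor} is set).
#' @slot p one-sided permutation p-value (+1 pseudo-count).
#' @slot nPerm number of permutations.
#' @slot alternative "greater" or "less".
#' @slot controlledFor label of the matrix partialled out, or "" for a plain
#'   Mantel test.
#' @exportClass MantelResult
setClass("MantelResult",
  representation(r = "numeric", p = "numeric", nPerm = "integer",
                 alternative = "character", controlledFor = "character")
)

setMethod("show", "MantelResult", function(object) {
  lab <- if (nzchar(object@controlledFor))
    sprintf("partial Mantel (controlled for %s)", object@controlledFor)
  else "Mantel"
  cat(sprintf("%s: r = %.3f, one-sided P = %.4g (%d permutations, alternative = %s)\n",
              lab, object@r, object@p, object@nPerm, object@alternative))
})

#' Spatial analysis of shared alleles (SAShA) result
#'
#' @slot OM observed mean geographic distance (km) between same-allele copies.
#' @slot EM expected mean distance under panmixia (km), weighted over loci by
#'   each locus's same-allele pair count.
#' @slot p two-sided permutation p-value for OM = EM.
#' @slot nPerm number of permutations.
#' @slot perLocus data.frame with per-locus OM, EM and pair weights.
#' @exportClass SashaResult
setClass("SashaResult",
  representation(OM = "numeric", EM = "numeric", p = "numeric",
                 nPerm = "integer", perLocus = "data.frame")
)

setMethod("show", "SashaResult", function(object) {
  cat(sprintf("SAShA: OM = %.1f km, EM = %.1f km, two-sided P = %.4g (%d permutations)\n",
              object@OM, object@EM, object@p, object@nPerm))
})
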
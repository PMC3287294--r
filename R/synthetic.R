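#' Simulation configuration for the Balding-Nichols genotype generator
#'
#' @param nPops populations (sampling sites) per species
#' @param nPerPop individuals per population; scalar or a matrix/vector giving
#'   per-species, per-population sizes (species in rows)
#' @param nLoci number of loci
#' @param allelesPerLocus visible alleles per locus (scalar or vector, >= 2)
#' @param F differentiation among populations within a species in [0, 1)
#'   (Balding-Nichols concentration; F = 0 means all populations share the
#'   ancestral frequencies exactly)
#' @param nullFreq null-allele frequency: scalar, per-locus vector, or a
#'   populations x loci matrix (recycled per species)
#' @param blankFailureRate probability of amplification failure independent
#'   of null alleles
#' @param nSpecies 1 or 2
#' @param Fsp between-species divergence (two independent Balding-Nichols
#'   draws from a common ancestral pool at this concentration)
#' @param sitePositionsKm site positions along a 1-D coastline (default
#'   evenly spaced by \code{spacingKm})
#' @param spacingKm spacing when positions are not given
#' @param gapAfter index such that an extra \code{gapKm} separates sites
#'   1..gapAfter from the rest (NULL = no gap)
#' @param gapKm width of the habitat gap
#' @param habitatCrossover probability that an individual is collected from
#'   the other species' typical habitat (species 1 = kelp-holdfast, species
#'   2 = rock)
#' @param seed RNG seed
#' @return a validated list of class \code{simConfig}
#' @export
simConfig <- function(nPops = 4L, nPerPop = 30L, nLoci = 7L,
                      allelesPerLocus = 10L, F = 0.01, nullFreq = 0,
                      blankFailureRate = 0, nSpecies = 1L, Fsp = 0.3,
                      sitePositionsKm = NULL, spacingKm = 100,
                      gapAfter = NULL, gapKm = 180,
                      habitatCrossover = 0.1, seed = 1L) {
  allelesPerLocus <- rep_len(as.integer(allelesPerLocus), nLoci)
  stopifnot(nPops >= 1L, nLoci >= 1L, all(allelesPerLocus >= 2L),
            F >= 0, F < 1, Fsp >= 0, Fsp < 1, nSpecies %in% c(1L, 2L),
            blankFailureRate >= 0, blankFailureRate <= 1)
  if (is.matrix(nPerPop)) stopifnot(nrow(nPerPop) == nSpecies, ncol(nPerPop) == nPops)
  else nPerPop <- matrix(rep_len(nPerPop, nSpecies * nPops), nSpecies, nPops, byrow = TRUE)
  if (is.matrix(nullFreq)) stopifnot(nrow(nullFreq) == nPops, ncol(nullFreq) == nLoci)
  else if (length(nullFreq) %in% c(1L, nLoci))
    nullFreq <- matrix(rep_len(nullFreq, nLoci), nPops, nLoci, byrow = TRUE)
  else if (length(nullFreq) == nPops)
    nullFreq <- matrix(nullFreq, nPops, nLoci)
  else stop("nullFreq must be a scalar, per-locus or per-population vector, or matrix")
  stopifnot(all(nullFreq >= 0 & nullFreq < 1))
  if (is.null(sitePositionsKm)) {
    sitePositionsKm <- (seq_len(nPops) - 1L) * spacingKm
    if (!is.null(gapAfter) && gapAfter < nPops)
      sitePositionsKm[(gapAfter + 1L):nPops] <-
        sitePositionsKm[(gapAfter + 1L):nPops] + gapKm
  }
  stopifnot(length(sitePositionsKm) == nPops)
  structure(list(nPops = as.integer(nPops), nPerPop = nPerPop,
                 nLoci = as.integer(nLoci), allelesPerLocus = allelesPerLocus,
                 F = F, nullFreq = nullFreq,
                 blankFailureRate = blankFailureRate,
                 nSpecies = as.integer(nSpecies), Fsp = Fsp,
                 sitePositionsKm = sitePositionsKm, gapAfter = gapAfter,
                 habitatCrossover = habitatCrossover,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Balding-Nichols draw: population frequencies around an ancestral vector at
# concentration (1-F)/F; F = 0 returns the ancestral vector unchanged.
bnDraw <- function(anc, F) {
  if (F == 0) return(anc)
  rdirichlet1(anc * (1 - F) / F)
}

#' Simulate a genotype dataset with known truth
#'
#' Island-model generator: per locus, ancestral visible-allele frequencies
#' are drawn from a symmetric Dirichlet(1); population frequencies follow a
#' Balding-Nichols Dirichlet around the ancestral vector at the configured F.
#' For two species, two independent ancestral vectors are drawn around a
#' common pool at divergence Fsp. True genotypes are drawn under HWE with a
#' null allele at the configured frequency; the observation model reports
#' visible/visible pairs, shows visible/null as an apparent homozygote,
#' blanks null/null, and blanks any locus independently at
#' \code{blankFailureRate}. Allele labels are integer "fragment sizes"
#' (100 + 2 x allele index; labels are per-marker, so loci may share values).
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{dataset} (\linkS4class{GenotypeData}) and
#'   \code{truth} (true frequencies, null frequencies, species labels, F)
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    L <- cfg$nLoci; P <- cfg$nPops; S <- cfg$nSpecies
    labels <- lapply(seq_len(L), function(l)
      as.integer(100 + 2 * seq_len(cfg$allelesPerLocus[l])))
    # ancestral and per-population visible-allele frequencies
    trueFreq <- vector("list", S)
    for (s in seq_len(S)) trueFreq[[s]] <- vector("list", L)
    for (l in seq_len(L)) {
      pool <- rdirichlet1(rep(1, cfg$allelesPerLocus[l]))
      for (s in seq_len(S)) {
        ancS <- if (S == 1L) pool else bnDraw(pool, cfg$Fsp)
        for (p in seq_len(P)) trueFreq[[s]][[l]][[p]] <- bnDraw(ancS, cfg$F)
      }
    }
    ids <- character(); siteOf <- character(); habitat <- character()
    speciesTrue <- character()
    A <- B <- NULL
    siteIds <- paste0("site", seq_len(P))
    for (s in seq_len(S)) for (p in seq_len(P)) {
      n <- cfg$nPerPop[s, p]
      if (n == 0L) next
      a <- b <- matrix(NA_integer_, n, L)
      for (l in seq_len(L)) {
        r <- cfg$nullFreq[p, l]
        fFull <- c(trueFreq[[s]][[l]][[p]] * (1 - r), r)   # last class = null
        nAll <- length(fFull)
        g1 <- sample.int(nAll, n, replace = TRUE, prob = fFull)
        g2 <- sample.int(nAll, n, replace = TRUE, prob = fFull)
        isNull1 <- g1 == nAll; isNull2 <- g2 == nAll
        av <- bv <- rep(NA_integer_, n)
        both <- !isNull1 & !isNull2
        av[both] <- labels[[l]][g1[both]]; bv[both] <- labels[[l]][g2[both]]
        one <- xor(isNull1, isNull2)                       # apparent homozygote
        vis <- ifelse(isNull1, g2, g1)
        av[one] <- bv[one] <- labels[[l]][vis[one]]
        fail <- runif(n) < cfg$blankFailureRate
        av[fail] <- bv[fail] <- NA_integer_
        a[, l] <- av; b[, l] <- bv
      }
      A <- rbind(A, a); B <- rbind(B, b)
      ids <- c(ids, sprintf("sp%d_%s_i%03d", s, siteIds[p], seq_len(n)))
      siteOf <- c(siteOf, rep(siteIds[p], n))
      speciesTrue <- c(speciesTrue, rep(paste0("species", s), n))
      typical <- if (s == 1L) "kelp-holdfast" else "rock"
      other <- if (s == 1L) "rock" else "kelp-holdfast"
      habitat <- c(habitat, ifelse(runif(n) < cfg$habitatCrossover, other, typical))
    }
    # sites on a meridian: convert coastline km to degrees of latitude
    kmPerDeg <- pi / 180 * 6371.0088
    sites <- data.frame(site_id = siteIds,
                        latitude = -46 + cfg$sitePositionsKm / kmPerDeg,
                        longitude = 170, stringsAsFactors = FALSE)
    markers <- setNames(labels, paste0("L", seq_len(L)))
    colnames(A) <- colnames(B) <- names(markers)
    individuals <- data.frame(id = ids, site_id = siteOf, habitat = habitat,
                              species = NA_character_, stringsAsFactors = FALSE)
    ds <- GenotypeData(A, B, individuals, sites, markers = markers)
    list(dataset = ds,
         truth = list(freq = trueFreq, nullFreq = cfg$nullFreq,
                      species = speciesTrue, F = cfg$F, Fsp = cfg$Fsp,
                      config = cfg))
  })
}

#' Convenience preset emulating the study's sampling design
#'
#' Two species sampled at the same 4 sites along a coastline with a 180-km
#' habitat gap between sites 1-3 and site 4; 7 loci with realistic allele
#' counts (5-41), per-population null-allele frequencies around 0.11-0.19,
#' weak within-species differentiation (F = 0.008) and strong between-species
#' divergence (Fsp = 0.3); about 10% independent amplification failure.
#'
#' @param seed RNG seed
#' @return list(dataset, truth) as in \code{\link{simulateGenotypes}}
#' @export
paperLikeDataset <- function(seed = 1L) {
  nPerPop <- rbind(c(18L, 43L, 28L, 35L),   # kelp-associated species
                   c(31L, 31L, 22L, 23L))   # rock-associated species
  nullByPop <- c(0.16, 0.15, 0.15, 0.17)
  cfg <- simConfig(
    nPops = 4L, nPerPop = nPerPop, nLoci = 7L,
    allelesPerLocus = c(17L, 38L, 13L, 39L, 16L, 7L, 41L),
    F = 0.008, nullFreq = matrix(nullByPop, 4L, 7L),
    blankFailureRate = 0.10, nSpecies = 2L, Fsp = 0.3,
    sitePositionsKm = c(0, 63, 150, 372), gapAfter = NULL,
    habitatCrossover = 0.12, seed = seed)
  simulateGenotypes(cfg)
}
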
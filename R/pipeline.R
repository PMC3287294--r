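#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of the full study workflow
#' (assignment, locus filtering, null-allele correction, differentiation
#' statistics, distances, spatial tests). All stage seeds derive from one
#' master seed so a rerun with the same configuration is bit-identical.
#'
#' @param dataset a \linkS4class{GenotypeData} (or a path to a genotype table
#'   CSV readable by \code{\link{readGenotypeTable}})
#' @param sitesPath optional sites CSV when \code{dataset} is a path
#' @param geoMatrix optional site-by-site geographic distance matrix in km
#'   (externally measured routes); default great-circle from site coordinates
#' @param gapGroups list(groupA=, groupB=) partition of site ids defining the
#'   habitat-discontinuity indicator, or NULL to skip gap tests
#' @param K clusters for the assignment stage
#' @param threshold Q-value threshold for species assignment
#' @param minLoci minimum scored loci per individual
#' @param minN minimum population sample size entering connectivity statistics
#' @param blankMode blank handling for the null-allele EM
#' @param nBoot bootstrap replicates for D and F_ST CIs
#' @param mantelPerms,sashaPerms permutation counts
#' @param mcmc list(nBurnin, nIter, nChains) for the assignment sampler
#' @param seed master seed
#' @return a list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(dataset, sitesPath = NULL, geoMatrix = NULL,
                           gapGroups = NULL, K = 2L, threshold = 0.8,
                           minLoci = 4L, minN = 10L,
                           blankMode = "blanks-as-nulls", nBoot = 1000L,
                           mantelPerms = 30000L, sashaPerms = 10000L,
                           mcmc = list(nBurnin = 2000L, nIter = 10000L, nChains = 5L),
                           seed = 1L) {
  structure(list(dataset = dataset, sitesPath = sitesPath,
                 geoMatrix = geoMatrix, gapGroups = gapGroups, K = K,
                 threshold = threshold, minLoci = minLoci, minN = minN,
                 blankMode = blankMode, nBoot = nBoot,
                 mantelPerms = mantelPerms, sashaPerms = sashaPerms,
                 mcmc = mcmc, seed = as.integer(seed)),
            class = "pipelineConfig")
}

mantelGrid <- function(mGen, mGeo, mGap, nPerm, seed) {
  rows <- list()
  addRow <- function(label, res)
    rows[[length(rows) + 1L]] <<- data.frame(
      variables = label, r = res@r, p = res@p, stringsAsFactors = FALSE)
  addRow("Gen,Geo", mantelTest(mGen, mGeo, nPerm, deriveSeed(seed, 1L)))
  if (!is.null(mGap)) {
    addRow("Gen,Geo|Gap", partialMantelTest(mGen, mGeo, mGap, nPerm,
                                            deriveSeed(seed, 2L),
                                            controlLabel = "Gap"))
    addRow("Gen,Gap", mantelTest(mGen, mGap, nPerm, deriveSeed(seed, 3L)))
    addRow("Gen,Gap|Geo", partialMantelTest(mGen, mGap, mGeo, nPerm,
                                            deriveSeed(seed, 4L),
                                            controlLabel = "Geo"))
  }
  do.call(rbind, rows)
}

#' Run the full comparative connectivity pipeline
#'
#' Stage order mirrors the study design: scored-locus filtering, genetic
#' species assignment (no-admixture clustering, Q threshold), exclusion of
#' AMBIGUOUS individuals and undersized populations, then per species:
#' null-allele EM correction, the differentiation report (H_S/H_T, Jost's D,
#' F_ST raw and ENA, G''_ST, N_m; global and pairwise), null-aware chord
#' distances, Mantel / partial Mantel tests against geographic distance and
#' the habitat gap, and SAShA.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return a study report: list with \code{crosstab}, \code{assignment},
#'   per-species \code{diffstats}, \code{dc}, \code{mantel}, \code{sasha},
#'   \code{nullAlleles}, plus \code{provenance} (seeds, sizes, excluded pops)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  x <- config$dataset
  if (is.character(x)) x <- readGenotypeTable(x, config$sitesPath)
  x <- filterByScoredLoci(x, config$minLoci)

  fit <- fitNoAdmixture(x, K = config$K,
                        nBurnin = config$mcmc$nBurnin,
                        nIter = config$mcmc$nIter,
                        nChains = config$mcmc$nChains,
                        seed = deriveSeed(config$seed, 11L))
  asg <- assignSpecies(fit, x, threshold = config$threshold)
  x <- asg$dataset
  speciesLabels <- setdiff(sort(unique(asg$assigned)), "AMBIGUOUS")

  geoAll <- config$geoMatrix
  if (is.null(geoAll)) geoAll <- greatCircleMatrix(x@sites)

  perSpecies <- list()
  for (sp in speciesLabels) {
    keep <- x@individuals$species == sp
    xs <- x[keep]
    tab <- table(popLabels(xs))
    pops <- names(tab)[tab >= config$minN]
    excluded <- setdiff(names(tab), pops)
    if (length(pops) < 2L) {
      perSpecies[[sp]] <- list(skipped = TRUE, reason = "fewer than 2 usable populations")
      next
    }
    xs <- xs[popLabels(xs) %in% pops]
    spSeed <- deriveSeed(config$seed, 100L + match(sp, speciesLabels))

    rmat <- nullAlleleTable(xs, pops, config$blankMode)
    ds <- pairwiseReport(xs, pops, nBoot = config$nBoot,
                         seed = deriveSeed(spSeed, 1L),
                         blankMode = config$blankMode)
    dc <- dcMatrix(xs, ina = TRUE, populations = pops,
                   blankMode = config$blankMode)
    geo <- geoAll[pops, pops, drop = FALSE]
    gap <- NULL
    if (!is.null(config$gapGroups)) {
      ga <- intersect(config$gapGroups$groupA, pops)
      gb <- intersect(config$gapGroups$groupB, pops)
      if (length(ga) && length(gb)) gap <- gapMatrix(pops, ga, gb)
    }
    mant <- mantelGrid(dc, geo, gap, config$mantelPerms, deriveSeed(spSeed, 2L))
    sas <- sasha(xs, geoMatrix = geo, nPerm = config$sashaPerms,
                 seed = deriveSeed(spSeed, 3L))
    perSpecies[[sp]] <- list(
      skipped = FALSE, populations = pops, excludedPops = excluded,
      nullAlleles = summarizeNullFrequencies(rmat), nullMatrix = rmat,
      diffstats = ds, dc = dc, mantel = mant,
      sasha = list(OM = sas@OM, EM = sas@EM, p = sas@p,
                   perLocus = sas@perLocus))
  }
  list(crosstab = asg$crosstab,
       assignment = list(Q = fit@Q, converged = fit@converged,
                         minChainCor = fit@minChainCor,
                         assigned = asg$assigned),
       species = perSpecies,
       provenance = list(seed = config$seed, nIndividuals = nInd(x),
                         threshold = config$threshold, minLoci = config$minLoci,
                         minN = config$minN, blankMode = config$blankMode,
                         nBoot = config$nBoot,
                         mantelPerms = config$mantelPerms,
                         sashaPerms = config$sashaPerms))
}

#' Write a study report to disk
#'
#' Serializes the report as JSON plus CSVs: the differentiation table, the
#' Mantel grid, the pairwise N_m matrix (with \code{"inf"} sentinel for
#' indefinite values) and the SAShA block, per species.
#'
#' @param report output of \code{\link{runPipeline}}
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(crosstab = as.data.frame(report$crosstab),
         provenance = report$provenance,
         species = lapply(report$species, function(s)
           if (isTRUE(s$skipped)) s else
             list(populations = s$populations,
                  nullAlleles = s$nullAlleles,
                  diffstats = s$diffstats, mantel = s$mantel,
                  sasha = s$sasha[c("OM", "EM", "p")]))),
    jsonPath, auto_unbox = TRUE, digits = NA)
  add(jsonPath)
  for (sp in names(report$species)) {
    s <- report$species[[sp]]
    if (isTRUE(s$skipped)) next
    f1 <- file.path(dir, paste0(sp, "_diffstats.csv"))
    write.csv(s$diffstats, f1, row.names = FALSE); add(f1)
    f2 <- file.path(dir, paste0(sp, "_mantel.csv"))
    write.csv(s$mantel, f2, row.names = FALSE); add(f2)
    nm <- matrix(NA_character_, length(s$populations), length(s$populations),
                 dimnames = list(s$populations, s$populations))
    pairRows <- s$diffstats[s$diffstats$scope != "global", ]
    for (i in seq_len(nrow(pairRows))) {
      pq <- strsplit(pairRows$scope[i], "|", fixed = TRUE)[[1]]
      v <- pairRows$Nm[i]
      nm[pq[1], pq[2]] <- nm[pq[2], pq[1]] <- if (is.infinite(v)) "inf" else format(v)
    }
    f3 <- file.path(dir, paste0(sp, "_nm_matrix.csv"))
    write.csv(as.data.frame(nm), f3, row.names = TRUE); add(f3)
    f4 <- file.path(dir, paste0(sp, "_sasha.csv"))
    write.csv(s$sasha$perLocus, f4, row.names = FALSE); add(f4)
  }
  invisible(paths)
}
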
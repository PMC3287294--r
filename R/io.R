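#' Read a Genepop file
#'
#' Parses the classic Genepop dialect: a title line, locus names (one per line
#' or comma-separated), \code{POP} separators, and individual rows of the form
#' \code{"id , 0102 0304 ..."} with 2- or 3-digit allele codes where
#' \code{00}/\code{000} encodes a blank locus. Populations are named
#' \code{pop1, pop2, ...} in file order and become sampling sites with unknown
#' coordinates; habitat is set to \code{"unknown"} (Genepop cannot carry it).
#'
#' @param path path to a Genepop (.gen) file
#' @return a \linkS4class{GenotypeData} object; allele codes are preserved as
#'   integer labels
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a Genepop file: too few lines")
  body <- lines[-1L]
  isPop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  firstPop <- which(isPop)[1L]
  if (is.na(firstPop)) stop("not a Genepop file: no POP separator found")
  locusLines <- body[seq_len(firstPop - 1L)]
  loci <- unlist(lapply(locusLines, function(s) trimws(strsplit(s, ",")[[1]])))
  loci <- loci[nzchar(loci)]
  nl <- length(loci)
  if (nl < 1L) stop("no locus names before the first POP separator")

  rows <- body[seq(firstPop, length(body))]
  rowIsPop <- grepl("^\\s*pop\\s*$", rows, ignore.case = TRUE)
  popIdx <- cumsum(rowIsPop)
  dataRows <- which(!rowIsPop)

  ids <- character(); popOf <- integer()
  A <- B <- matrix(NA_integer_, nrow = 0L, ncol = nl)
  digitsPerLocus <- rep(NA_integer_, nl)
  for (ri in dataRows) {
    line <- rows[ri]
    halves <- strsplit(line, ",")[[1]]
    if (length(halves) < 2L)
      stop("malformed Genepop row (missing ','): line ", ri + 1L)
    id <- trimws(halves[1L])
    geno <- strsplit(trimws(paste(halves[-1L], collapse = ",")), "\\s+")[[1]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != nl)
      stop(sprintf("line %d ('%s'): expected %d genotypes, found %d",
                   ri + 1L, id, nl, length(geno)))
    a <- b <- integer(nl)
    for (l in seq_len(nl)) {
      tok <- geno[l]
      if (!grepl("^[0-9]+$", tok) || !(nchar(tok) %in% c(4L, 6L)))
        stop(sprintf("line %d, locus %s: bad genotype code '%s'", ri + 1L, loci[l], tok))
      d <- nchar(tok) / 2L
      if (is.na(digitsPerLocus[l])) digitsPerLocus[l] <- d
      else if (digitsPerLocus[l] != d)
        stop(sprintf("locus %s mixes %d- and %d-digit allele coding",
                     loci[l], digitsPerLocus[l], d))
      a[l] <- as.integer(substr(tok, 1L, d))
      b[l] <- as.integer(substr(tok, d + 1L, 2L * d))
    }
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    if (any(is.na(a) != is.na(b)))
      stop(sprintf("line %d ('%s'): half-missing genotype is malformed", ri + 1L, id))
    ids <- c(ids, id); popOf <- c(popOf, popIdx[ri])
    A <- rbind(A, a); B <- rbind(B, b)
  }
  popNames <- paste0("pop", seq_len(max(popOf)))
  individuals <- data.frame(id = ids, site_id = popNames[popOf],
                            habitat = "unknown", species = NA_character_,
                            stringsAsFactors = FALSE)
  if (anyDuplicated(individuals$id))
    individuals$id <- make.unique(individuals$id, sep = "_")
  sites <- data.frame(site_id = popNames, latitude = NA_real_,
                      longitude = NA_real_, stringsAsFactors = FALSE)
  colnames(A) <- colnames(B) <- loci
  GenotypeData(A, B, individuals, sites)
}

#' Write a Genepop file
#'
#' @param x a \linkS4class{GenotypeData}
#' @param path output path
#' @param digits allele-code width (2 or 3; default 3, accommodating fragment
#'   sizes up to 999 bp)
#' @param title title line
#' @return invisibly, \code{path}
#' @export
writeGenepop <- function(x, path, digits = 3L, title = "raftgen export") {
  stopifnot(digits %in% c(2L, 3L))
  maxAll <- suppressWarnings(max(unlist(x@markers), na.rm = TRUE))
  if (is.finite(maxAll) && maxAll >= 10^digits)
    stop("allele labels exceed the chosen Genepop code width")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(markerNames(x), con)
  fmt <- paste0("%0", digits, "d")
  pops <- unique(popLabels(x))
  for (p in pops) {
    writeLines("POP", con)
    idx <- which(popLabels(x) == p)
    for (i in idx) {
      a <- x@alleleA[i, ]; b <- x@alleleB[i, ]
      code <- ifelse(is.na(a), strrep("0", 2L * digits),
                     paste0(sprintf(fmt, a), sprintf(fmt, b)))
      writeLines(paste0(x@individuals$id[i], " , ", paste(code, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read / write a delimited genotype table
#'
#' The table format is lossless (unlike Genepop it carries habitat labels):
#' columns \code{individual_id}, \code{site_id}, \code{habitat}, optionally
#' \code{species}, then two columns per locus named \code{<locus>.a} /
#' \code{<locus>.b}; blank loci are empty/NA in both columns. Site coordinates
#' travel in a companion sites CSV (\code{site_id}, \code{latitude},
#' \code{longitude}).
#'
#' @param path genotype table path (CSV)
#' @param sitesPath optional sites CSV; when absent, sites are inferred from
#'   the table with unknown coordinates
#' @return a \linkS4class{GenotypeData}
#' @export
readGenotypeTable <- function(path, sitesPath = NULL) {
  tb <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("individual_id", "site_id", "habitat", "species"), names(tb))
  if (!all(c("individual_id", "site_id", "habitat") %in% meta))
    stop("genotype table must have columns individual_id, site_id, habitat")
  if (anyDuplicated(tb$individual_id))
    stop("duplicate individual_id in genotype table")
  gcols <- setdiff(names(tb), meta)
  if (length(gcols) %% 2L != 0L) stop("odd number of genotype columns")
  aCols <- gcols[grepl("\\.a$", gcols)]
  loci <- sub("\\.a$", "", aCols)
  bCols <- paste0(loci, ".b")
  if (!all(bCols %in% gcols)) stop("genotype columns must come in <locus>.a/<locus>.b pairs")
  A <- as.matrix(tb[, aCols, drop = FALSE]); B <- as.matrix(tb[, bCols, drop = FALSE])
  storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  colnames(A) <- colnames(B) <- loci
  individuals <- data.frame(id = tb$individual_id, site_id = tb$site_id,
                            habitat = tb$habitat,
                            species = if ("species" %in% meta) tb$species else NA_character_,
                            stringsAsFactors = FALSE)
  if (!is.null(sitesPath)) {
    sites <- read.csv(sitesPath, stringsAsFactors = FALSE)
    names(sites)[names(sites) == "lat"] <- "latitude"
    names(sites)[names(sites) == "lon"] <- "longitude"
  } else {
    sites <- data.frame(site_id = unique(individuals$site_id),
                        latitude = NA_real_, longitude = NA_real_,
                        stringsAsFactors = FALSE)
  }
  GenotypeData(A, B, individuals, sites)
}

#' @rdname readGenotypeTable
#' @param x a \linkS4class{GenotypeData}
#' @export
writeGenotypeTable <- function(x, path, sitesPath = NULL) {
  out <- data.frame(individual_id = x@individuals$id,
                    site_id = x@individuals$site_id,
                    habitat = x@individuals$habitat,
                    species = x@individuals$species,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in markerNames(x)) {
    out[[paste0(l, ".a")]] <- x@alleleA[, l]
    out[[paste0(l, ".b")]] <- x@alleleB[, l]
  }
  write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(sitesPath))
    write.csv(x@sites, sitesPath, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop individuals scored at too few loci
#'
#' Retains exactly the individuals with at least \code{minLoci} non-missing
#' genotypes (the study pipeline uses 4 of 7). Sites that lose all their
#' individuals stay in the site metadata.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param minLoci minimum number of scored loci (>= 0)
#' @return the filtered \linkS4class{GenotypeData}
#' @export
filterByScoredLoci <- function(x, minLoci = 4L) {
  stopifnot(minLoci >= 0)
  keep <- scoredLoci(x) >= minLoci
  x[keep]
}
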
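# Small constructors used across the suite.

# Build a GenotypeData from allele matrices and a population vector.
mkData <- function(a, b, pop, lat = NULL, lon = NULL, habitat = "unknown") {
  a <- as.matrix(a); b <- as.matrix(b)
  ids <- sprintf("ind%03d", seq_len(nrow(a)))
  sitesIds <- unique(pop)
  if (is.null(lat)) lat <- rep(NA_real_, length(sitesIds))
  if (is.null(lon)) lon <- rep(NA_real_, length(sitesIds))
  GenotypeData(a, b,
    individuals = data.frame(id = ids, site_id = pop,
                             habitat = rep_len(habitat, nrow(a)),
                             stringsAsFactors = FALSE),
    sites = data.frame(site_id = sitesIds, latitude = lat, longitude = lon,
                       stringsAsFactors = FALSE))
}

# One-population, one-locus dataset from explicit genotype pairs (NA = blank).
mkCell <- function(pairs) {
  a <- vapply(pairs, `[`, 0, 1); b <- vapply(pairs, `[`, 0, 2)
  mkData(matrix(a), matrix(b), rep("p1", length(a)))
}

# Draw one population x locus cell with a null allele: nAlleles equifrequent
# visible alleles, null frequency r, n individuals, observation model as in
# the generator (visible/null -> apparent homozygote, null/null -> blank).
drawNullCell <- function(n, nAlleles, r, seed) {
  set.seed(seed)
  f <- c(rep((1 - r) / nAlleles, nAlleles), r)
  lab <- c(100 + 2 * seq_len(nAlleles), NA)
  g1 <- sample.int(nAlleles + 1L, n, replace = TRUE, prob = f)
  g2 <- sample.int(nAlleles + 1L, n, replace = TRUE, prob = f)
  a <- lab[g1]; b <- lab[g2]
  oneNull <- xor(is.na(a), is.na(b))
  vis <- ifelse(is.na(a), b, a)
  a[oneNull] <- b[oneNull] <- vis[oneNull]
  mkData(matrix(a), matrix(b), rep("p1", n))
}

# Independent random symmetric distance matrix with zero diagonal.
randDist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  m
}
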
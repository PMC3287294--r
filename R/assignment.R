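#' No-admixture Bayesian clustering by Gibbs sampling
#'
#' Assigns individuals to K genetic clusters under the classic no-admixture,
#' independent-allele-frequency model: each individual belongs wholly to one
#' cluster; cluster allele frequencies get a symmetric Dirichlet(lambda)
#' prior; genotypes follow within-cluster Hardy-Weinberg proportions (p_a^2
#' homozygote, 2 p_a p_b heterozygote); missing loci contribute likelihood 1.
#' The Gibbs sampler alternates (i) p_k,l ~ Dirichlet(lambda + allele counts
#' of the individuals currently in k) and (ii) z_i sampled proportionally to
#' the multilocus genotype likelihood with a uniform label prior. Q_i,k is
#' the posterior frequency of z_i = k over post-burn-in sweeps. Label
#' switching is resolved by greedily matching each sweep's cluster frequency
#' vectors to the previous accepted orientation by minimal total-variation
#' distance; chains are aligned to the first chain the same way, and the
#' final Q averages the chains.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param K number of clusters
#' @param lambda Dirichlet prior parameter (> 0)
#' @param nBurnin,nIter burn-in and recorded MCMC sweeps
#' @param nChains independent chains (distinct sub-seeds)
#' @param seed RNG seed
#' @param convergenceR minimum pairwise Pearson correlation of chain Q
#'   vectors below which a convergence warning is flagged
#' @return an \linkS4class{AssignmentResult}
#' @export
fitNoAdmixture <- function(x, K = 2L, lambda = 1.0, nBurnin = 2000L,
                           nIter = 10000L, nChains = 5L, seed = NULL,
                           convergenceR = 0.99) {
  stopifnot(K >= 1L, lambda > 0, nIter > 0L, nInd(x) > 0L)
  N <- nInd(x); L <- nLoci(x)
  # per-locus integer-coded calls
  aIdx <- bIdx <- matrix(NA_integer_, N, L)
  nAll <- integer(L)
  for (l in seq_len(L)) {
    uni <- x@markers[[l]]
    nAll[l] <- length(uni)
    aIdx[, l] <- match(x@alleleA[, l], uni)
    bIdx[, l] <- match(x@alleleB[, l], uni)
  }
  scored <- lapply(seq_len(L), function(l) which(!is.na(aIdx[, l])))
  isHet <- aIdx != bIdx
  log2v <- log(2)

  if (K == 1L) {
    Q <- matrix(1, N, 1L, dimnames = list(x@individuals$id, "cluster1"))
    return(new("AssignmentResult", Q = Q, chainQ = list(Q),
               assigned = character(0), threshold = NA_real_,
               converged = TRUE, minChainCor = 1))
  }

  perms <- allPerms(K)

  runChain <- function(chainSeed) {
    withSeed(chainSeed, {
      z <- sample.int(K, N, replace = TRUE)
      Qcount <- matrix(0, N, K)
      prevP <- NULL
      for (sweep in seq_len(nBurnin + nIter)) {
        # (i) sample cluster allele frequencies
        P <- vector("list", L)
        for (l in seq_len(L)) {
          idx <- scored[[l]]
          pl <- matrix(0, nAll[l], K)
          for (k in seq_len(K)) {
            inK <- idx[z[idx] == k]
            cnt <- tabulate(c(aIdx[inK, l], bIdx[inK, l]), nbins = nAll[l])
            pl[, k] <- rdirichlet1(lambda + cnt)
          }
          P[[l]] <- pl
        }
        # (ii) sample labels from the genotype likelihood
        ll <- matrix(0, N, K)
        for (l in seq_len(L)) {
          idx <- scored[[l]]
          lp <- log(pmax(P[[l]], 1e-300))
          for (k in seq_len(K)) {
            ll[idx, k] <- ll[idx, k] + lp[aIdx[idx, l], k] + lp[bIdx[idx, l], k] +
              log2v * isHet[idx, l]
          }
        }
        g <- -log(-log(matrix(runif(N * K), N, K)))   # Gumbel-max sampling
        z <- max.col(ll + g)
        if (sweep > nBurnin) {
          # label alignment against the previous accepted orientation
          pflat <- do.call(rbind, P)                  # states x K
          if (is.null(prevP)) {
            perm <- seq_len(K)
          } else {
            costs <- vapply(perms, function(pm)
              sum(abs(pflat[, pm] - prevP)) / 2, numeric(1))
            perm <- perms[[which.min(costs)]]
          }
          prevP <- pflat[, perm, drop = FALSE]
          zAligned <- match(z, perm)
          Qcount[cbind(seq_len(N), zAligned)] <- Qcount[cbind(seq_len(N), zAligned)] + 1
        }
      }
      Qcount / nIter
    })
  }

  chainQ <- lapply(seq_len(nChains), function(cidx)
    runChain(deriveSeed(if (is.null(seed)) sample.int(2^30, 1) else seed, cidx)))

  # align chains 2..n to chain 1 by minimal total |Q| difference
  ref <- chainQ[[1L]]
  for (ci in seq_along(chainQ)[-1L]) {
    costs <- vapply(perms, function(pm)
      sum(abs(chainQ[[ci]][, pm] - ref)), numeric(1))
    chainQ[[ci]] <- chainQ[[ci]][, perms[[which.min(costs)]], drop = FALSE]
  }
  minCor <- 1
  if (length(chainQ) > 1L) {
    for (i in seq_along(chainQ)) for (j in seq_len(i - 1L)) {
      minCor <- min(minCor, cor(as.vector(chainQ[[i]]), as.vector(chainQ[[j]])))
    }
  }
  converged <- minCor >= convergenceR
  if (!converged)
    warning(sprintf("chains may not have converged (min Q correlation %.3f)", minCor))
  Q <- Reduce(`+`, chainQ) / length(chainQ)
  dimnames(Q) <- list(x@individuals$id, paste0("cluster", seq_len(K)))
  chainQ <- lapply(chainQ, function(q) { dimnames(q) <- dimnames(Q); q })
  new("AssignmentResult", Q = Q, chainQ = chainQ, assigned = character(0),
      threshold = NA_real_, converged = converged, minChainCor = minCor)
}

#' Threshold-based species assignment from cluster memberships
#'
#' Individuals whose maximum Q exceeds the threshold get that cluster's
#' label; the rest (including exact ties at the threshold) are AMBIGUOUS and
#' are meant to be excluded from downstream statistics. Also emits the
#' cross-tabulation of assigned label against collection habitat.
#'
#' @param result an \linkS4class{AssignmentResult}
#' @param x the \linkS4class{GenotypeData} the result was fitted on
#' @param threshold Q-value needed to qualify (in (0.5, 1]; default 0.8;
#'   strictly-greater comparison, so Q exactly at the threshold is AMBIGUOUS)
#' @param labels optional cluster label names (default cluster1..K)
#' @return list with \code{dataset} (species column filled; AMBIGUOUS kept
#'   but labelled), \code{crosstab} (species x habitat), \code{assigned}
#'   label vector
#' @export
assignSpecies <- function(result, x, threshold = 0.8, labels = NULL) {
  stopifnot(threshold > 0.5, threshold <= 1)
  Q <- result@Q
  if (nrow(Q) != nInd(x)) stop("result and dataset sizes differ")
  K <- ncol(Q)
  if (is.null(labels)) labels <- colnames(Q)
  top <- max.col(Q, ties.method = "first")
  qmax <- Q[cbind(seq_len(nrow(Q)), top)]
  assigned <- ifelse(qmax > threshold, labels[top], "AMBIGUOUS")
  x@individuals$species <- assigned
  crosstab <- table(species = assigned, habitat = x@individuals$habitat)
  list(dataset = x, crosstab = crosstab, assigned = assigned)
}
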
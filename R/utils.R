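#' @import methods
#' @importFrom stats cor pt quantile rbeta rgamma rmultinom runif sd setNames var
#' @importFrom utils combn read.csv write.csv
NULL

# Upper-triangle (i < j) entries of a square matrix, column-major order.
upperTri <- function(m) m[upper.tri(m)]

# Deterministic sub-seed derivation so that one user-facing seed can drive
# several internal RNG streams without them colliding. Stays within 32-bit
# integer range.
deriveSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629) + 1L
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Symmetric Dirichlet / general Dirichlet draw via gamma normalization.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {
    # all-underflow guard: fall back to the normalized shape vector
    return(alpha / sum(alpha))
  }
  g / s
}

# All permutations of 1:n (n small; used for label alignment and the
# exhaustive Mantel enumeration in tests).
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- allPerms(n - 1L)
    for (p in rest) {
      v <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, v[p])
    }
  }
  out
}

checkSquareLabelled <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  }
  m
}
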
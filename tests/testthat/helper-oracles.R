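# Independent oracles used to cross-check the package's statistics.
# Each is deliberately implemented by a different route than the code
# under test (direct summation, brute-force scans, enumeration).

# binomial upper tail P(X >= k) by direct term-wise log-space summation
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Poisson upper tail P(X >= k) by direct series summation of the complement
oraclePoisTail <- function(k, lambda) {
  if (k <= 0) return(1)
  ks <- 0:(k - 1)
  1 - sum(exp(ks * log(lambda) - lambda - lgamma(ks + 1)))
}

# Benjamini-Hochberg step-up by the textbook loop
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# reciprocal-overlap sharing by brute-force double loop on raw coordinates
# (0-based half-open); returns logical matrix [i, j]
oracleReciprocal <- function(a, b, minFrac = 0.5) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
    la <- a$end[i] - a$start[i]
    lb <- b$end[j] - b$start[j]
    out[i, j] <- (ov / la > minFrac) && (ov / lb > minFrac)
  }
  out
}

# nearest gene by exhaustive scan on raw 0-based coordinates
oracleNearest <- function(eChrom, eStart, eEnd, genes) {
  best <- NULL; bestD <- Inf
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != eChrom) next
    d <- if (eStart < genes$end[j] && genes$start[j] < eEnd) 0
    else max(genes$start[j] - eEnd, eStart - genes$end[j])
    if (d < bestD || (d == bestD && genes$id[j] < best)) {
      best <- genes$id[j]; bestD <- d
    }
  }
  list(id = best, distance = bestD)
}

# Monte-Carlo permutation p for the rank-sum statistic (handles ties);
# used where exact enumeration needs an independent check under ties
oracleRankSumMC <- function(x, y, B = 2e5, seed = 99) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  dev <- abs(U - mu)
  hits <- replicate(B, {
    rp <- sample(r)
    abs(sum(rp[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu) >= dev - 1e-9
  })
  mean(hits)
}

# small genome simulation used across tests
tinyConfig <- function(seed = 1, ...) {
  args <- list(nChroms = 1L, chromLength = 6e5, nGenes = 40L,
               nEnhancers = 5L, nInputFrags = 2e4L, nCdnaFrags = 2e4L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}
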
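test_that("duplicate removal keys on (chrom, start, end, strand)", {
  raw <- c(bedRanges("chr1", rep(0, 3), rep(600, 3), strand = "+"),
           bedRanges("chr1", 100, 700, strand = "+"))
  lib <- dedupFragments(raw)
  expect_equal(totalUnique(lib), 2L)
  # same coordinates, opposite strand: both retained
  two <- dedupFragments(c(bedRanges("chr1", 0, 600, strand = "+"),
                          bedRanges("chr1", 0, 600, strand = "-")))
  expect_equal(totalUnique(two), 2L)
  empty <- dedupFragments(GRanges())
  expect_equal(totalUnique(empty), 0L)
})

test_that("midpoint counting assigns boundaries rightward and conserves totals", {
  asm <- genomeAssembly("chr1", 1800)
  bins <- binGenome(asm, 600)
  lib <- dedupFragments(bedRanges("chr1", 0, 600))
  expect_equal(countMidpoints(lib, bins), c(1L, 0L, 0L))
  # fragment [300,900): midpoint 600 belongs to bin [600,1200)
  lib <- dedupFragments(bedRanges("chr1", 300, 900))
  expect_equal(countMidpoints(lib, bins), c(0L, 1L, 0L))
  # conservation: n fragments in one bin
  n <- 17
  raw <- bedRanges("chr1", seq(10, 10 + n - 1), seq(110, 110 + n - 1))
  counts <- countMidpoints(dedupFragments(raw), bins)
  expect_equal(sum(counts), n)
  expect_equal(counts[1], n)
})

test_that("midpoint counting conserves totals on simulated libraries", {
  sim <- simulateGenome(tinyConfig(seed = 10))
  lib <- simulateFragments(sim, "input", n = 3000)
  bins <- binGenome(sim$assembly, 600)
  expect_equal(sum(countMidpoints(lib, bins)), totalUnique(lib))
})

test_that("window statistics match exact binomial tails and the strength definition", {
  s <- windowStats(5, 5, 100, 100)
  expect_equal(s$strength, 1.0)
  expect_equal(s$p_value, oracleBinomTail(5, 100, 0.05), tolerance = 1e-12)
  expect_equal(round(s$p_value, 4), 0.5640)

  s <- windowStats(10, 2, 1000, 1000)
  expect_equal(s$strength, 5.0)
  expect_equal(s$p_value, oracleBinomTail(10, 1000, 0.002), tolerance = 1e-12)

  # empty upper tail includes all mass
  s0 <- windowStats(0, 5, 100, 100)
  expect_equal(s0$strength, 0)
  expect_equal(s0$p_value, 1)

  # pseudo-count substitutes only for zero input
  sz <- windowStats(3, 0, 100, 200)
  expect_equal(sz$strength, (3 / 100) / (1 / 200))
  expect_error(windowStats(1, 1, 0, 100), "totals")
})

test_that("binomial p is monotone non-increasing in the cDNA count", {
  p <- sapply(0:30, function(k) windowStats(k, 5, 1000, 1000)$p_value)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (n in c(3, 17, 200, 1000)) {
    p <- runif(n)^sample(1:3, 1)
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("q-values are in [0,1] and monotone in p rank on scored windows", {
  sim <- simulateGenome(tinyConfig(seed = 12))
  inp <- simulateFragments(sim, "input")
  cdn <- simulateFragments(sim, "cdna", pool = inp)
  sw <- scoreWindows(cdn, inp, sim$assembly)
  m <- mcols(sw)
  q <- m$q_value[!is.na(m$q_value)]
  p <- m$p_value[!is.na(m$q_value)]
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # untested windows (no fragments at all) have NA q
  expect_true(all(is.na(m$q_value[m$cdna_count + m$input_count == 0])))
})

.mkStats <- function(strength, p, q, width = 600, gap = 0) {
  n <- length(strength)
  starts <- cumsum(c(0, rep(width + gap, n - 1)))
  gr <- bedRanges(rep("chr1", n), starts, starts + width)
  mcols(gr) <- DataFrame(cdna_count = rep(1L, n), input_count = rep(1L, n),
                         strength = strength, p_value = p, q_value = q)
  gr
}

test_that("calling applies strict thresholds and merges adjacent windows", {
  # no window passes
  none <- callEnhancers(.mkStats(c(0.5, 0.9), c(1e-5, 1e-5), c(0.01, 0.01)))
  expect_equal(length(none), 0L)
  # strength exactly 1.0 is excluded
  expect_equal(length(callEnhancers(.mkStats(1.0, 1e-6, 1e-4))), 0L)
  expect_equal(length(callEnhancers(.mkStats(1.0 + 1e-9, 1e-6, 1e-4))), 1L)
  # two abutting significant windows merge into one 1200 bp call
  merged <- callEnhancers(.mkStats(c(3, 4), c(1e-6, 1e-8), c(1e-4, 1e-6)))
  expect_equal(length(merged), 1L)
  expect_equal(width(merged), 1200L)
  expect_equal(mcols(merged)$strength, 4)
  expect_equal(mcols(merged)$best_p, 1e-8)
  expect_equal(mcols(merged)$best_q, 1e-6)
  # p and q thresholds are both required
  expect_equal(length(callEnhancers(.mkStats(3, 0.01, 1e-4))), 0L)
  expect_equal(length(callEnhancers(.mkStats(3, 1e-6, 0.5))), 0L)
})

test_that("replicate concordance matches Pearson limits and exclusion rule", {
  a <- .mkStats(c(1, 2, 3, 4), rep(0.5, 4), rep(0.5, 4))
  expect_equal(replicateConcordance(a, a), 1.0)
  b <- .mkStats(c(2, 4, 6, 8), rep(0.5, 4), rep(0.5, 4))
  expect_equal(replicateConcordance(a, b, scale = "linear"), 1.0)
  neg <- .mkStats(c(8, 6, 4, 2), rep(0.5, 4), rep(0.5, 4))
  expect_equal(replicateConcordance(a, neg, scale = "linear"), -1.0)
  # windows empty in both replicates are excluded
  a2 <- a; b2 <- b
  mcols(a2)$cdna_count[1] <- 0L; mcols(a2)$input_count[1] <- 0L
  mcols(b2)$cdna_count[1] <- 0L; mcols(b2)$input_count[1] <- 0L
  mcols(a2)$strength[1] <- 99  # must be ignored
  expect_equal(replicateConcordance(a2, b2, scale = "linear"), 1.0)
  one <- .mkStats(1, 0.5, 0.5)
  expect_error(replicateConcordance(one, one), "fewer than 2")
})

test_that("consensus and union sets follow the reciprocal-overlap rules", {
  A <- bedRanges("chr1", 0, 1000)
  B <- bedRanges("chr1", 200, 800)
  # shared at > 50% reciprocal overlap, collapsed to the union span
  sh <- consensusCalls(A, B)
  expect_equal(length(sh), 1L)
  expect_equal(bedStart(sh), 0)
  expect_equal(bedEnd(sh), 1000)
  # disjoint sets: nothing shared, union keeps both
  C <- bedRanges("chr1", 5000, 5600)
  expect_equal(length(consensusCalls(A, C)), 0L)
  expect_equal(length(unionCalls(c(A, C))), 2L)
  # identical sets: shared = union = set
  expect_equal(length(consensusCalls(A, A)), 1L)
  # abutting calls are NOT merged in the union (> 0 bp rule)
  ab <- c(bedRanges("chr1", 0, 600), bedRanges("chr1", 600, 1200))
  expect_equal(length(unionCalls(ab)), 2L)
  ov <- c(bedRanges("chr1", 0, 600), bedRanges("chr1", 599, 1200))
  expect_equal(length(unionCalls(ov)), 1L)
})

test_that("consensus agrees with a brute-force pairwise reciprocal check", {
  set.seed(11)
  for (rep in 1:5) {
    mk <- function(n) {
      s <- sample(0:20000, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                 start = s, end = s + sample(300:1500, n, TRUE))
    }
    da <- mk(30); db <- mk(30)
    ga <- bedRanges(da$chrom, da$start, da$end)
    gb <- bedRanges(db$chrom, db$start, db$end)
    want <- oracleReciprocal(da, db)
    sh <- consensusCalls(ga, gb)
    # every brute-force shared pair is covered by a consensus span
    for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
      if (want[i, j]) {
        span <- bedRanges(da$chrom[i], min(da$start[i], db$start[j]),
                          max(da$end[i], db$end[j]))
        expect_true(any(overlapBp(rep(span, length(sh)), sh) == width(span)))
      }
    }
    expect_equal(length(sh) > 0, any(want))
  }
})

test_that("cross-source consensus map produces per-cell-line, shared and union sets", {
  r1 <- c(bedRanges("chr1", 0, 600), bedRanges("chr1", 5000, 5600))
  r2 <- c(bedRanges("chr1", 0, 600), bedRanges("chr1", 9000, 9600))
  s2 <- bedRanges("chr1", 100, 700)
  out <- consensusAndUnion(list(cellA = list(rep1 = r1, rep2 = r2),
                                cellB = list(rep1 = s2, rep2 = s2)))
  expect_equal(length(out$perCellLine$cellA), 1L)   # only [0,600) replicates
  expect_equal(length(out$perCellLine$cellB), 1L)
  expect_equal(length(out$shared), 1L)              # 600/700 > 0.5 both ways
  expect_equal(length(out$union), 3L)
  expect_equal(unname(out$counts[["union"]]), 3L)
})
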
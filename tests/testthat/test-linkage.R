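test_that("QTL length filter keeps regions up to exactly half a chromosome", {
  asm <- genomeAssembly("chr1", 1e6)
  q <- bedRanges("chr1", c(0, 0, 100), c(5e5, 1e6, 200))
  mcols(q)$trait <- c("a", "b", "c")
  kept <- filterQtls(q, asm)
  expect_equal(mcols(kept)$trait, c("a", "c"))  # exactly half retained
  expect_identical(filterQtls(kept, asm), kept)  # idempotent
  expect_equal(length(filterQtls(q[0], asm)), 0L)
  bad <- bedRanges("chrX", 0, 100)
  mcols(bad)$trait <- "x"
  expect_error(filterQtls(bad, asm), "unknown chromosome")
})

test_that("QTL-enhancer overlap counts non-redundant regions and distinct traits", {
  enh <- bedRanges("chr1", 1000, 1600)
  q1 <- bedRanges("chr1", 500, 2000); mcols(q1)$trait <- "growth"
  r <- qtlEnhancerOverlap(q1, enh)
  expect_equal(r$nNonredundantQtls, 1L)
  expect_equal(r$nTraits, 1L)
  # duplicate coordinates with different traits: 1 region, 2 traits
  q2 <- c(q1, q1); mcols(q2)$trait <- c("growth", "backfat")
  r <- qtlEnhancerOverlap(q2, enh)
  expect_equal(r$nNonredundantQtls, 1L)
  expect_equal(r$nTraits, 2L)
  # no overlap -> zeros
  far <- bedRanges("chr1", 90000, 95000); mcols(far)$trait <- "z"
  r <- qtlEnhancerOverlap(far, enh)
  expect_equal(c(r$nNonredundantQtls, r$nTraits), c(0L, 0L))
  # merge-overlapping alternative collapses overlapping distinct records
  q3 <- c(q1, bedRanges("chr1", 800, 2500))
  mcols(q3)$trait <- c("growth", "growth")
  expect_equal(qtlEnhancerOverlap(q3, enh)$nNonredundantQtls, 2L)
  expect_equal(qtlEnhancerOverlap(q3, enh, mergeOverlapping = TRUE)$nNonredundantQtls,
               1L)
})

test_that("TAD co-membership requires both midpoints in one TAD", {
  tads <- bedRanges("chr1", c(0, 1e6), c(1e6, 2e6))
  a <- bedRanges("chr1", 100000, 100600)
  b <- bedRanges("chr1", 800000, 800600)
  expect_true(sameTad(a, b, tads))
  c_ <- bedRanges("chr1", 1200000, 1200600)
  expect_false(sameTad(a, c_, tads))
  d <- bedRanges("chr2", 100000, 100600)
  expect_false(sameTad(a, d, tads))
  ovl <- bedRanges("chr1", c(0, 5e5), c(1e6, 2e6))
  expect_error(sameTad(a, b, ovl), "overlapping TADs")
})

test_that("contact significance is an exact distance-stratified Poisson tail", {
  asm <- genomeAssembly("chr1", 400000)
  z <- matrix(0, 10, 10)
  cm <- contactMatrix(list(chr1 = z), 40000L, asm)
  a <- bedRanges("chr1", 10000, 10600)
  b <- bedRanges("chr1", 250000, 250600)
  r <- contactSignificance(cm, a, b)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)  # P(X >= 0) = 1

  # expected 2, observed 10: exact series complement
  m <- matrix(2, 10, 10)
  i <- 1; j <- 7  # distance 6
  m[i, j] <- 10; m[j, i] <- 10
  d <- abs(row(m) - col(m))
  expd <- mean(m[d == 6])
  cm <- contactMatrix(list(chr1 = m), 40000L, asm)
  r <- contactSignificance(cm, bedRanges("chr1", 0, 600),
                           bedRanges("chr1", 240000, 240600))
  expect_equal(r$expected, expd)
  expect_equal(r$p_value, oraclePoisTail(10, expd), tolerance = 1e-12)

  # constant matrix: nothing significant at 0.05 at any distance
  k <- matrix(50, 50, 50)
  cmk <- contactMatrix(list(chr1 = k), 40000L, genomeAssembly("chr1", 2e6))
  ps <- sapply(1:49, function(jj) {
    contactSignificance(cmk, bedRanges("chr1", 0, 600),
                        bedRanges("chr1", (jj) * 40000, (jj) * 40000 + 600))$p_value
  })
  expect_true(all(ps > 0.05))
  expect_true(all(ps <= 1))
  expect_error(contactSignificance(cmk, bedRanges("chr1", 0, 600),
                                   bedRanges("chr2", 0, 600)), "same chromosome")
})

test_that("contact p is monotone non-increasing in the observed count", {
  ps <- sapply(0:30, function(o) {
    stats::ppois(o - 1, lambda = 5, lower.tail = FALSE)
  })
  asm <- genomeAssembly("chr1", 400000)
  got <- sapply(0:30, function(o) {
    m <- matrix(5, 10, 10); m[1, 4] <- o; m[4, 1] <- o
    cm <- contactMatrix(list(chr1 = m), 40000L, asm)
    contactSignificance(cm, bedRanges("chr1", 0, 600),
                        bedRanges("chr1", 120000, 120600))$p_value
  })
  expect_true(all(diff(got) <= 1e-12))
})

test_that("trait links require QTL overlap and flag only same-TAD significant contacts", {
  sim <- simulateGenome(tinyConfig(seed = 17))
  hic <- simulateHic(sim, resolution = 20000L)
  genes <- sim$geneModel$genes
  # QTL over an enhancer but excluding a distant gene -> no link to that gene
  enh <- sim$truth[1]
  q <- GRanges(seqnames(enh), IRanges(start(enh) - 1000, end(enh) + 1000))
  mcols(q)$trait <- "t"
  links <- linkEnhancers(enh, q, genes, hic$tads, hic$contacts)
  inQtl <- countOverlaps(genes, q) > 0
  expect_true(all(links$gene %in% mcols(genes)$gene_id[inQtl]))
  # candidate is the conjunction: same_tad FALSE is never flagged
  expect_true(all(!links$candidate[!links$same_tad]))
  expect_true(all(links$candidate == (links$same_tad & links$contact_p < 0.05)))
})

test_that("planted Hi-C boosts are recovered as flagged candidates", {
  recovered <- 0L
  for (s in 1:5) {
    sim <- simulateGenome(simConfig(seed = s))
    hic <- simulateHic(sim)
    qtls <- filterQtls(simulateQtls(sim), sim$assembly)
    links <- linkEnhancers(sim$truth, qtls, sim$geneModel$genes,
                           hic$tads, hic$contacts)
    tr <- mcols(sim$truth)
    li <- which(!is.na(tr$linked_gene))
    ok <- mapply(function(e, g)
      any(links$enhancer == e & links$gene == g & links$candidate),
      tr$name[li], tr$linked_gene[li])
    if (all(ok)) recovered <- recovered + 1L
  }
  expect_gte(recovered, 4L)
})

test_that("null matrices without boosts flag links at about the nominal rate", {
  # flat distance decay, no TAD elevation, no planted links: the fraction
  # of same-TAD pairs with contact p < alpha stays near alpha
  alpha <- 0.05
  rates <- sapply(1:20, function(s) {
    sim <- simulateGenome(tinyConfig(seed = s + 100))
    hic <- simulateHic(sim, resolution = 20000L, seed = s + 100,
                       tadBoost = 1,
                       links = data.frame(chrom = character(),
                                          binA = integer(), binB = integer()))
    m <- hic$contacts@matrices$chr1
    nb <- nrow(m)
    d <- abs(row(m) - col(m))
    flags <- 0L; tested <- 0L
    for (dd in 2:6) {
      expd <- mean(m[d == dd])
      idx <- which(d == dd & upper.tri(m))
      p <- stats::ppois(m[idx] - 1, lambda = expd, lower.tail = FALSE)
      flags <- flags + sum(p < alpha)
      tested <- tested + length(idx)
    }
    c(flags, tested)
  })
  rate <- sum(rates[1, ]) / sum(rates[2, ])
  se <- sqrt(alpha * (1 - alpha) / sum(rates[2, ]))
  expect_lte(rate, alpha + 3 * se)
})
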
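test_that("genome simulation is deterministic and honors its contracts", {
  cfg <- tinyConfig(seed = 1)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(a$repeats, b$repeats)
  expect_identical(a$truth, b$truth)
  expect_identical(a$geneModel$genes, b$geneModel$genes)

  # planted-enhancer contract
  expect_equal(length(a$truth), 5L)
  expect_true(all(width(a$truth) == 600L))
  expect_true(all(mcols(a$truth)$activity >= 3 &
                    mcols(a$truth)$activity <= 6))

  # repeat fraction within +/- 2% of target
  frac <- coveredBp(a$repeats) / 6e5
  expect_lt(abs(frac - 0.45), 0.02)

  # genes non-overlapping with TSS inside the span
  expect_equal(length(reduce(a$geneModel$genes, ignore.strand = TRUE,
                             min.gapwidth = 0L)),
               length(a$geneModel$genes))
  expect_true(all(mcols(a$geneModel$genes)$tss >= bedStart(a$geneModel$genes) &
                    mcols(a$geneModel$genes)$tss < bedEnd(a$geneModel$genes)))

  # no repeats requested -> none placed
  none <- simulateGenome(tinyConfig(seed = 2, repeatFraction = 0))
  expect_equal(length(none$repeats), 0L)
})

test_that("different seeds give different genomes", {
  a <- simulateGenome(tinyConfig(seed = 1))
  b <- simulateGenome(tinyConfig(seed = 2))
  expect_false(identical(start(a$truth), start(b$truth)))
})

test_that("fragment libraries match the length model and are seed-stable", {
  sim <- simulateGenome(tinyConfig(seed = 3))
  lib <- simulateFragments(sim, "input", n = 5000)
  expect_s4_class(lib, "FragmentLibrary")
  expect_equal(totalUnique(lib), 5000L)
  w <- width(fragments(lib))
  expect_true(all(w >= 200 & w <= 1200))
  expect_lt(abs(mean(w) - 600), 15)
  lib2 <- simulateFragments(sim, "input", n = 5000)
  expect_identical(fragments(lib), fragments(lib2))
  empty <- simulateFragments(sim, "input", n = 0)
  expect_equal(totalUnique(empty), 0L)
})

test_that("cDNA enrichment matches the weighted-sampling expectation", {
  # one 600 bp enhancer of activity 4 in a 1 Mb genome: expected
  # cdna/input midpoint-count ratio in that bin = 4/(1 + 3*600/1e6) ~ 3.99
  cfg <- simConfig(nChroms = 1L, chromLength = 1e6, nGenes = 20L,
                   nEnhancers = 1L, activityRange = c(4, 4),
                   nInputFrags = 1000000L, nCdnaFrags = 1000000L, seed = 11L)
  sim <- simulateGenome(cfg)
  inp <- simulateFragments(sim, "input")
  cdn <- simulateFragments(sim, "cdna", pool = inp)
  enh <- sim$truth[1]
  nIn <- sum(countOverlaps(midpointRanges(fragments(inp)), enh) > 0)
  nCd <- sum(countOverlaps(midpointRanges(fragments(cdn)), enh) > 0)
  ratio <- nCd / nIn
  expect_lt(abs(ratio - 4 / (1 + 3 * 600 / 1e6)), 0.35)  # ~3 MC SDs
})

test_that("null libraries are exchangeable: per-bin strength centers on 1", {
  cfg <- tinyConfig(seed = 4, activityRange = c(1, 1))
  sim <- simulateGenome(cfg)
  inp <- simulateFragments(sim, "input")
  cdn <- simulateFragments(sim, "cdna", pool = inp)
  sw <- scoreWindows(cdn, inp, sim$assembly)
  s <- mcols(sw)$strength[mcols(sw)$input_count > 0]
  expect_lt(abs(mean(s) - 1), 0.05)
})

test_that("input fragment placement is positionally uniform under the null", {
  # chi-square over 600 bp bins should not reject at alpha = 0.01 in the
  # vast majority of seeds
  rejections <- 0L
  for (s in 1:10) {
    sim <- simulateGenome(tinyConfig(seed = s))
    lib <- simulateFragments(sim, "input")
    bins <- binGenome(sim$assembly, 600L)
    counts <- countMidpoints(lib, bins)
    expected <- totalUnique(lib) * width(bins) / 6e5
    stat <- sum((counts - expected)^2 / expected)
    pval <- pchisq(stat, df = length(bins) - 1, lower.tail = FALSE)
    if (pval < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("chromatin tracks plant peaks only where the truth carries the mark", {
  sim <- simulateGenome(tinyConfig(seed = 5, openFraction = 1))
  tr <- simulateTracks(sim, "ATAC")
  expect_equal(length(tr$peaks), length(sim$truth))
  expect_true(all(countOverlaps(sim$truth, tr$peaks) > 0))
  inputTr <- simulateTracks(sim, "INPUT")
  expect_equal(length(inputTr$peaks), 0L)
  # planted fold >= 3 over matched INPUT at the enhancer
  folds <- foldEnrichment(tr$track, inputTr$track, sim$truth)
  expect_true(all(folds >= 3))
  # no truth flags -> no peaks
  simClosed <- simulateGenome(tinyConfig(seed = 5, openFraction = 0))
  expect_equal(length(simulateTracks(simClosed, "ATAC")$peaks), 0L)
  expect_error(simulateTracks(sim, "H3K4me2"), "unknown mark")
  # seeded reproducibility
  tr2 <- simulateTracks(sim, "ATAC")
  expect_identical(tr$track@values, tr2$track@values)
})

test_that("Hi-C matrices are symmetric with decay, TAD blocks and boosted links", {
  sim <- simulateGenome(tinyConfig(seed = 6))
  hic <- simulateHic(sim, resolution = 20000L)
  m <- hic$contacts@matrices$chr1
  expect_identical(m, t(m))
  expect_true(all(m >= 0))
  # distance decay: near-diagonal mean greatly exceeds far-field mean
  d <- abs(row(m) - col(m))
  expect_gt(mean(m[d == 1]), mean(m[d == 10]))
  expect_error(simulateHic(sim, resolution = 6e5), "at least 2 bins")

  # planted link boost: mean observed/expected over seeds approaches beta
  ratios <- sapply(1:20, function(s) {
    sm <- simulateGenome(tinyConfig(seed = s))
    link <- data.frame(chrom = "chr1", binA = 3L, binB = 12L)
    h <- simulateHic(sm, resolution = 20000L, seed = s, tadBoost = 1,
                     beta = 5, links = link)
    mm <- h$contacts@matrices$chr1
    dd <- abs(row(mm) - col(mm))
    base <- mean(mm[dd == 9 & !(row(mm) %in% c(3, 12) & col(mm) %in% c(3, 12))])
    mm[3, 12] / base
  })
  expect_lt(abs(mean(ratios) - 5), 1)

  # no boosts: observed/expected ratio consistent with 1
  nullRatios <- sapply(1:10, function(s) {
    sm <- simulateGenome(tinyConfig(seed = s))
    h <- simulateHic(sm, resolution = 20000L, seed = s, tadBoost = 1,
                     links = data.frame(chrom = character(), binA = integer(),
                                        binB = integer()))
    mm <- h$contacts@matrices$chr1
    dd <- abs(row(mm) - col(mm))
    mm[3, 12] / mean(mm[dd == 9])
  })
  expect_lt(abs(mean(nullRatios) - 1), 0.3)
})

test_that("expression simulation honors the silent fraction exactly at the limits", {
  sim <- simulateGenome(tinyConfig(seed = 7))
  allSilent <- simulateExpression(sim, silentFraction = 1)
  expect_true(all(allSilent == 0))
  none <- simulateExpression(sim, silentFraction = 0)
  expect_true(all(none > 0))
  x1 <- simulateExpression(sim)
  x2 <- simulateExpression(sim)
  expect_identical(x1, x2)
})

test_that("simulated QTLs cover planted links and include oversized regions", {
  sim <- simulateGenome(simConfig(seed = 8))
  q <- simulateQtls(sim)
  planted <- q[mcols(q)$source == "planted"]
  li <- which(!is.na(mcols(sim$truth)$linked_gene))
  expect_equal(length(planted), length(li))
  expect_true(all(countOverlaps(sim$truth[li], planted) > 0))
  sl <- seqlengths(sim$assembly)
  expect_true(any(width(q) > 0.5 * sl[as.character(seqnames(q))]))
})

test_that("a written study is byte-reproducible for a fixed config", {
  cfg <- tinyConfig(seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudy(simulateStudy(cfg, cellLines = "cellA", replicates = "rep1"), d1)
  writeStudy(simulateStudy(cfg, cellLines = "cellA", replicates = "rep1"), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})
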
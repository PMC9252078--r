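# The enhancer caller: per-window midpoint counts of cDNA vs input-plasmid
# fragments, strength (fold change of normalized counts), a binomial
# upper-tail test per window, BH FDR control, merging of significant
# windows, replicate concordance, and consensus/union set construction.

#' Remove duplicate fragments
#'
#' Retains exactly one fragment per identical (chrom, start, end, strand)
#' tuple — the in-silico analogue of PCR duplicate removal — and records
#' the unique total used as the library size.
#'
#' @param raw `GRanges` of raw fragment intervals (strand-aware), or a
#'   [FragmentLibrary-class] to deduplicate in place.
#' @param label,replicate,cellLine provenance for the returned library
#'   (ignored when `raw` is already a `FragmentLibrary`).
#' @return A [FragmentLibrary-class] with `totalUnique` set.
#' @export
dedupFragments <- function(raw, label = "input", replicate = "rep1",
                           cellLine = "cellA") {
  if (is(raw, "FragmentLibrary")) {
    label <- raw@label; replicate <- raw@replicate; cellLine <- raw@cellLine
    raw <- raw@fragments
  }
  key <- paste(as.character(seqnames(raw)), start(raw), end(raw),
               as.character(strand(raw)), sep = ":")
  uniq <- raw[!duplicated(key)]
  fragmentLibrary(uniq, label = label, replicate = replicate,
                  cellLine = cellLine)
}

#' Count fragment midpoints per genome bin
#'
#' Each fragment is assigned to the unique bin containing its midpoint
#' `floor((start + end)/2)` (BED coordinates; a midpoint on a bin boundary
#' belongs to the right-hand bin). Midpoint assignment rather than overlap
#' counting keeps the per-library total conserved: fragments of ~600 bp in
#' 600 bp bins would otherwise be double-counted.
#'
#' @param lib a [FragmentLibrary-class] (or bare `GRanges`).
#' @param bins a genome tiling from [binGenome()].
#' @return Integer vector of counts, one per bin; sums to the library
#'   total.
#' @export
countMidpoints <- function(lib, bins) {
  gr <- if (is(lib, "FragmentLibrary")) fragments(lib) else lib
  binChrom <- as.character(seqnames(bins))
  w <- width(bins)[1]
  # per-chromosome offsets into the bin vector; bins must tile the genome
  rle <- S4Vectors::runValue(seqnames(bins))
  counts <- integer(length(bins))
  if (length(gr) == 0) return(counts)
  nPer <- table(factor(binChrom, levels = unique(binChrom)))
  off <- stats::setNames(cumsum(c(0, as.integer(nPer)[-length(nPer)])),
                         names(nPer))
  mid0 <- midpointBed(gr)
  ch <- as.character(seqnames(gr))
  if (!all(ch %in% names(off)))
    stop("fragment on a chromosome absent from the bin tiling")
  maxMid <- tapply(bedEnd(bins), binChrom, max)
  if (any(mid0 >= maxMid[ch]) || any(mid0 < 0))
    stop("fragment midpoint outside the genome (corrupt input)")
  idx <- off[ch] + mid0 %/% w + 1L
  tab <- tabulate(idx, nbins = length(bins))
  as.integer(tab)
}

#' Window strength and binomial significance
#'
#' Strength is the fold change of library-normalized counts,
#' `(cdna/cdnaTotal) / (max(input, pseudo)/inputTotal)`; the p-value is the
#' upper tail `P(X >= cdna)` for `X ~ Binomial(cdnaTotal, p0)` with null
#' success probability `p0 = max(input, pseudo)/inputTotal` (the
#' BasicSTARRseq-style null: every cDNA fragment falls in the window with
#' the input library's window fraction). The tail is computed exactly via
#' the stable upper-tail complement, never a normal approximation. The
#' pseudo-count substitutes for the input count only when it is zero,
#' avoiding infinite strength while remaining conservative.
#'
#' @param cdnaCount,inputCount per-window midpoint counts (vectorized).
#' @param cdnaTotal,inputTotal library totals (> 0).
#' @param pseudo pseudo-count applied when `inputCount` is 0 (default 1).
#' @return `data.frame(strength, p_value)`.
#' @examples
#' windowStats(5, 5, 100, 100)   # strength 1, p = P(Bin(100, .05) >= 5)
#' @export
windowStats <- function(cdnaCount, inputCount, cdnaTotal, inputTotal,
                        pseudo = 1) {
  if (cdnaTotal <= 0 || inputTotal <= 0)
    stop("library totals must be > 0")
  if (pseudo < 0) stop("pseudo must be >= 0")
  inp <- pmax(inputCount, pseudo)
  strength <- (cdnaCount / cdnaTotal) / (inp / inputTotal)
  p0 <- inp / inputTotal
  p <- stats::pbinom(cdnaCount - 1, cdnaTotal, p0, lower.tail = FALSE)
  data.frame(strength = strength, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} n p_(j) / j`, capped at
#' 1, returned in input order. Input p-values outside [0, 1] are rejected.
#'
#' @param p numeric vector of p-values.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score genome windows for enhancer activity
#'
#' Tiles the genome, counts cDNA and input fragment midpoints per window,
#' computes strength and binomial p per window, and BH-adjusts the
#' p-values over informative windows only (windows with
#' `cdna + input > 0`; empty windows carry no information and would dilute
#' the FDR correction — their q is NA).
#'
#' @param cdna,input [FragmentLibrary-class] objects.
#' @param assembly a `Seqinfo`.
#' @param windowWidth window width in bp (600 as in the study this
#'   implements).
#' @param pseudo zero-input pseudo-count.
#' @return `GRanges` of windows with metadata `cdna_count`, `input_count`,
#'   `strength`, `p_value`, `q_value`.
#' @export
scoreWindows <- function(cdna, input, assembly, windowWidth = 600L,
                         pseudo = 1) {
  stopifnot(libraryLabel(cdna) == "cdna", libraryLabel(input) == "input")
  bins <- binGenome(assembly, windowWidth)
  cc <- countMidpoints(cdna, bins)
  ic <- countMidpoints(input, bins)
  st <- windowStats(cc, ic, totalUnique(cdna), totalUnique(input), pseudo)
  q <- rep(NA_real_, length(bins))
  tested <- cc + ic > 0
  q[tested] <- bhFdr(st$p_value[tested])
  mcols(bins) <- DataFrame(cdna_count = cc, input_count = ic,
                           strength = st$strength, p_value = st$p_value,
                           q_value = q)
  bins
}

#' Call enhancers from scored windows
#'
#' Windows passing all of strength > `minStrength` (strictly — a window at
#' exactly 1.0 is excluded), p < `maxP` and q < `maxFdr` are selected, and
#' adjacent or overlapping significant windows are merged into a single
#' call whose strength is the maximum constituent window strength and
#' whose best p/q are the minima.
#'
#' @param windows scored windows from [scoreWindows()].
#' @param minStrength,maxP,maxFdr the calling thresholds (defaults 1.0,
#'   0.001, 0.1 — the study's published criteria).
#' @param provenance label recorded on each call.
#' @return `GRanges` of calls with `name`, `strength`, `best_p`, `best_q`,
#'   `provenance` metadata.
#' @export
callEnhancers <- function(windows, minStrength = 1.0, maxP = 0.001,
                          maxFdr = 0.1, provenance = "cellA/rep1") {
  m <- mcols(windows)
  sig <- !is.na(m$q_value) & m$strength > minStrength &
    m$p_value < maxP & m$q_value < maxFdr
  sel <- windows[sig]
  if (length(sel) == 0) {
    out <- GRanges()
    mcols(out) <- DataFrame(name = character(), strength = numeric(),
                            best_p = numeric(), best_q = numeric(),
                            provenance = character())
    return(out)
  }
  merged <- reduce(granges(sel), ignore.strand = TRUE)  # merges abutting bins
  hit <- findOverlaps(sel, merged, ignore.strand = TRUE)
  j <- factor(S4Vectors::subjectHits(hit), levels = seq_along(merged))
  mcols(merged) <- DataFrame(
    name = sprintf("enhancer_%04d", seq_along(merged)),
    strength = as.numeric(tapply(mcols(sel)$strength, j, max)),
    best_p = as.numeric(tapply(mcols(sel)$p_value, j, min)),
    best_q = as.numeric(tapply(mcols(sel)$q_value, j, min)),
    provenance = provenance)
  merged
}

#' Replicate concordance of window strengths
#'
#' Pearson correlation of per-window strengths between two replicates.
#' Windows with zero counts in both libraries of both replicates are
#' excluded (they carry no signal); by default the correlation is computed
#' on `log2(strength + eps)` since fold changes are ratio-scaled, with the
#' linear scale available.
#'
#' @param statsA,statsB scored windows from [scoreWindows()] on the same
#'   tiling.
#' @param scale "log2" (default) or "linear".
#' @param eps offset inside the log (default 0.01).
#' @return Pearson r.
#' @export
replicateConcordance <- function(statsA, statsB, scale = c("log2", "linear"),
                                 eps = 0.01) {
  scale <- match.arg(scale)
  if (length(statsA) != length(statsB))
    stop("window tilings differ")
  a <- mcols(statsA); b <- mcols(statsB)
  use <- (a$cdna_count + a$input_count > 0) | (b$cdna_count + b$input_count > 0)
  if (sum(use) < 2) stop("fewer than 2 usable windows")
  x <- a$strength[use]; y <- b$strength[use]
  if (scale == "log2") { x <- log2(x + eps); y <- log2(y + eps) }
  stats::cor(x, y)
}

#' Consensus and union of enhancer call sets
#'
#' `consensusCalls`: pairs of calls from two sources sharing strictly more
#' than `minReciprocal` reciprocal overlap, each matched pair collapsed to
#' the union span. `unionCalls`: all calls self-merged at > 0 bp overlap
#' into non-redundant intervals (abutting calls stay separate).
#' `consensusAndUnion` applies both across a two-level map of sources:
#' replicate consensus within each cell line, cross-cell-line shared set,
#' and the non-redundant union, with per-source counts.
#'
#' @param a,b `GRanges` of calls from two sources.
#' @param minReciprocal reciprocal-overlap fraction (default 0.5; strict).
#' @return `consensusCalls`/`unionCalls`: `GRanges`.
#' @export
consensusCalls <- function(a, b, minReciprocal = 0.5) {
  if (length(a) == 0 || length(b) == 0) return(GRanges())
  hit <- findOverlaps(a, b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  ok <- reciprocalOverlap(a[qi], b[si], minFrac = minReciprocal)
  if (!any(ok)) return(GRanges())
  qi <- qi[ok]; si <- si[ok]
  spans <- GRanges(seqnames(a)[qi],
                   IRanges(pmin(start(a)[qi], start(b)[si]),
                           pmax(end(a)[qi], end(b)[si])))
  unionCalls(spans)
}

#' @rdname consensusCalls
#' @param calls `GRanges` (or list of `GRanges`) of calls to merge.
#' @export
unionCalls <- function(calls) {
  if (is.list(calls) || is(calls, "GRangesList"))
    calls <- suppressWarnings(do.call(c, lapply(unname(as.list(calls)), granges)))
  if (length(calls) == 0) return(GRanges())
  # min.gapwidth = 0 merges only genuinely overlapping (> 0 bp) intervals
  reduce(granges(calls), ignore.strand = TRUE, min.gapwidth = 0L)
}

#' @rdname consensusCalls
#' @param callsBySource nested list `[[cellLine]][[replicate]]` of call
#'   `GRanges`.
#' @return `consensusAndUnion`: list with `perCellLine` (replicate
#'   consensus per cell line), `shared` (cross-cell-line consensus),
#'   `union` (non-redundant union of all calls), and `counts`.
#' @export
consensusAndUnion <- function(callsBySource, minReciprocal = 0.5) {
  perCellLine <- lapply(callsBySource, function(reps) {
    reps <- lapply(reps, granges)
    if (length(reps) == 1) return(reps[[1]])
    Reduce(function(a, b) consensusCalls(a, b, minReciprocal), reps)
  })
  shared <- if (length(perCellLine) >= 2)
    Reduce(function(a, b) consensusCalls(a, b, minReciprocal), perCellLine)
  else perCellLine[[1]]
  allCalls <- unlist(lapply(callsBySource, function(reps)
    lapply(reps, granges)), recursive = FALSE)
  un <- unionCalls(allCalls)
  counts <- c(vapply(perCellLine, length, 1L),
              shared = length(shared), union = length(un))
  list(perCellLine = perCellLine, shared = shared, union = un,
       counts = counts)
}

#' Match calls against planted truth
#'
#' Benchmark helper: a planted enhancer is recovered when at least one
#' call shares strictly more than `minReciprocal` reciprocal overlap with
#' it; a call matching no planted enhancer is a false call.
#'
#' @param calls,truth `GRanges`.
#' @param minReciprocal reciprocal-overlap match criterion (default 0.5).
#' @return List with `sensitivity`, `fdr`, `nCalls`, `nTruth`.
#' @export
matchCalls <- function(calls, truth, minReciprocal = 0.5) {
  if (length(truth) == 0) stop("empty truth set")
  if (length(calls) == 0)
    return(list(sensitivity = 0, fdr = 0, nCalls = 0L,
                nTruth = length(truth)))
  hit <- findOverlaps(calls, truth, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  ok <- reciprocalOverlap(calls[qi], truth[si], minFrac = minReciprocal)
  list(sensitivity = length(unique(si[ok])) / length(truth),
       fdr = 1 - length(unique(qi[ok])) / length(calls),
       nCalls = length(calls), nTruth = length(truth))
}
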
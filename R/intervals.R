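#' Build a genome assembly descriptor
#'
#' Stands in for a reference assembly: ordered chromosome names with
#' positive lengths, as a `Seqinfo`.
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths integer vector of lengths in bp.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' genomeAssembly(c("chr1", "chr2"), c(3e6, 2.5e6))
#' @export
genomeAssembly <- function(chromNames, chromLengths) {
  if (anyDuplicated(chromNames))
    stop("chromosome names must be unique")
  if (any(chromLengths <= 0))
    stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = as.character(chromNames),
          seqlengths = as.integer(chromLengths))
}

#' Construct intervals from BED-style (0-based half-open) coordinates
#'
#' The package stores intervals as `GRanges` (1-based closed); this is the
#' single conversion point from the BED convention used by all on-disk
#' formats. `start0 < end0` is required (empty intervals are invalid).
#'
#' @param chrom character vector of chromosome names.
#' @param start0 0-based inclusive starts.
#' @param end0 exclusive ends.
#' @param strand "+", "-" or "." (unstranded); recycled.
#' @param seqinfo optional `Seqinfo` for bounds validation.
#' @return A `GRanges`.
#' @examples
#' bedRanges("chr1", 0, 600)   # chr1:[0,600) -> 600 bp
#' @export
bedRanges <- function(chrom, start0, end0, strand = ".", seqinfo = NULL) {
  if (any(start0 < 0)) stop("start must be >= 0")
  if (any(start0 >= end0)) stop("start must be < end (empty interval)")
  st <- ifelse(strand == ".", "*", strand)
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0), strand = st)
  if (!is.null(seqinfo)) {
    bad <- end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]
    if (any(is.na(bad)) || any(bad))
      stop("interval outside assembly bounds")
    seqinfo(gr) <- seqinfo[seqlevels(gr)]
  }
  gr
}

#' BED-style start/end of intervals
#'
#' @param gr a `GRanges`.
#' @return `bedStart`: 0-based inclusive starts; `bedEnd`: exclusive ends.
#' @export
bedStart <- function(gr) start(gr) - 1L

#' @rdname bedStart
#' @export
bedEnd <- function(gr) end(gr)

#' Pairwise overlap in base pairs
#'
#' Element-wise overlap between two interval vectors (recycled like
#' arithmetic). Strand-agnostic; intervals on different chromosomes
#' overlap by 0. Under the half-open convention, abutting intervals
#' ([0,600) vs [600,900)) overlap by 0.
#'
#' @param a,b `GRanges` of equal (or recyclable) length.
#' @return Integer vector of overlap widths in bp.
#' @examples
#' overlapBp(bedRanges("chr1", 0, 600), bedRanges("chr1", 300, 900))  # 300
#' @export
overlapBp <- function(a, b) {
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Reciprocal-overlap test for shared intervals
#'
#' Two intervals are "shared" when their intersection covers strictly more
#' than `minFrac` of each (the strict inequality matters: a pair at exactly
#' 50/50 reciprocal overlap is not shared at `minFrac = 0.5`).
#'
#' @param a,b `GRanges`, element-wise.
#' @param minFrac fraction in (0, 1]; default 0.5.
#' @param strict use strict `>` (default) or `>=`.
#' @return Logical vector.
#' @examples
#' a <- bedRanges("chr1", 0, 1000); b <- bedRanges("chr1", 200, 800)
#' reciprocalOverlap(a, b)               # TRUE (0.6 and 1.0 both > 0.5)
#' reciprocalOverlap(bedRanges("chr1", 0, 600),
#'                   bedRanges("chr1", 300, 900))  # FALSE: 0.5 is not > 0.5
#' @export
reciprocalOverlap <- function(a, b, minFrac = 0.5, strict = TRUE) {
  if (any(minFrac <= 0) || any(minFrac > 1))
    stop("minFrac must lie in (0, 1]")
  ov <- overlapBp(a, b)
  fa <- ov / width(a)
  fb <- ov / width(b)
  if (strict) fa > minFrac & fb > minFrac else fa >= minFrac & fb >= minFrac
}

#' Tile a genome into fixed-width bins
#'
#' Non-overlapping tiles per chromosome; the last tile of each chromosome
#' is truncated at the chromosome end, so the tiles partition every base
#' exactly once.
#'
#' @param assembly a `Seqinfo`.
#' @param width tile width in bp (> 0).
#' @return `GRanges` of tiles, ordered by (chromosome, start).
#' @examples
#' binGenome(genomeAssembly("chr1", 1500), 600)  # [0,600) [600,1200) [1200,1500)
#' @export
binGenome <- function(assembly, width) {
  if (width <= 0) stop("width must be > 0")
  sl <- seqlengths(assembly)
  parts <- lapply(seqlevels(assembly), function(ch) {
    s0 <- seq(0, sl[[ch]] - 1, by = width)
    GRanges(ch, IRanges(s0 + 1, pmin(s0 + width, sl[[ch]])))
  })
  tiles <- suppressWarnings(do.call(c, parts))
  seqinfo(tiles) <- assembly
  tiles
}

#' Total bases covered by the union of an interval set
#'
#' Internal overlaps are merged before summing, so duplicated or
#' overlapping intervals are not double-counted.
#'
#' @param gr a `GRanges` (may be empty).
#' @return Covered bp as a numeric scalar.
#' @examples
#' coveredBp(bedRanges(c("chr1", "chr1"), c(0, 50), c(100, 150)))  # 150
#' @export
coveredBp <- function(gr) {
  if (length(gr) == 0) return(0)
  sum(as.numeric(width(reduce(gr, ignore.strand = TRUE))))
}

#' Fragment/interval midpoints (BED convention)
#'
#' The midpoint of `[start, end)` is `floor((start + end) / 2)` in 0-based
#' coordinates; a midpoint falling on a bin boundary belongs to the
#' right-hand bin.
#'
#' @param gr a `GRanges`.
#' @return Integer vector of 0-based midpoint positions.
#' @export
midpointBed <- function(gr) {
  as.integer((bedStart(gr) + bedEnd(gr)) %/% 2L)
}

#' @rdname midpointBed
#' @return `midpointRanges`: width-1 `GRanges` at each midpoint.
#' @export
midpointRanges <- function(gr) {
  m <- midpointBed(gr)
  GRanges(seqnames(gr), IRanges(m + 1L, width = 1L))
}
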
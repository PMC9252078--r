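# Chromatin integration: accessibility split, ChIP/INPUT fold enrichment,
# +/- 5 kb profile matrices, rank-sum comparisons between open and closed
# enhancers, and chromatin-state classification.

.activeMarks <- c("H3K4me1", "H3K4me3", "H3K27ac")
.repressiveMarks <- c("H3K9me3", "H3K27me3")

#' Classify enhancers as open or closed chromatin
#'
#' An enhancer is "open" when it overlaps an ATAC-seq accessible-chromatin
#' peak by at least 1 bp (a half-open abutting peak does not count), else
#' "closed".
#'
#' @param enhancers `GRanges`.
#' @param atacPeaks `GRanges` of accessible regions.
#' @return Factor of "open"/"closed", one per enhancer.
#' @export
classifyAccessibility <- function(enhancers, atacPeaks) {
  open <- countOverlaps(enhancers, atacPeaks, ignore.strand = TRUE) > 0
  factor(ifelse(open, "open", "closed"), levels = c("open", "closed"))
}

# bp-weighted mean of a binned track over a BED interval [s0, e0)
.trackMean <- function(track, chrom, s0, e0) {
  v <- track@values[[chrom]]
  if (is.null(v)) stop("region on a chromosome outside track coverage")
  L <- seqlengths(track@seqinfo)[[chrom]]
  if (s0 < 0 || e0 > L) stop("region outside track coverage")
  w <- track@binWidth
  b0 <- s0 %/% w
  b1 <- (e0 - 1) %/% w
  idx <- b0:b1
  lo <- pmax(s0, idx * w)
  hi <- pmin(e0, (idx + 1) * w)
  sum(v[idx + 1] * (hi - lo)) / (e0 - s0)
}

#' ChIP/INPUT fold enrichment over a region
#'
#' `(mean chip + pseudo) / (mean input + pseudo)` over the region, with
#' means taken bp-weighted over the shared track binning. The pseudo-count
#' (default 0.1) regularizes regions where either track is near zero; in
#' the large-signal limit the fold is scale-free.
#'
#' @param chip,input [SignalTrack-class] on the same binning.
#' @param region a single-interval `GRanges` (vectorized over regions).
#' @param pseudo regularizing pseudo-signal.
#' @return Numeric fold enrichment per region.
#' @export
foldEnrichment <- function(chip, input, region, pseudo = 0.1) {
  if (chip@binWidth != input@binWidth)
    stop("tracks must share the same binning")
  vapply(seq_along(region), function(i) {
    ch <- as.character(seqnames(region))[i]
    s0 <- bedStart(region)[i]; e0 <- bedEnd(region)[i]
    (.trackMean(chip, ch, s0, e0) + pseudo) /
      (.trackMean(input, ch, s0, e0) + pseudo)
  }, 1.0)
}

#' Fold-enrichment profile matrix around enhancer midpoints
#'
#' For each enhancer, ChIP/INPUT fold enrichment in `2*flank/bin` bins of
#' `bin` bp centered on the enhancer midpoint (100 bins of 100 bp spanning
#' +/- 5 kb by default). Enhancers whose window would cross a chromosome
#' edge are dropped and counted. The column-wise mean profile is attached.
#'
#' @param enhancers `GRanges`.
#' @param chip,input [SignalTrack-class].
#' @param flank half-width of the window in bp.
#' @param bin profile bin width in bp; must divide `flank`.
#' @param pseudo passed to [foldEnrichment()].
#' @return List with `matrix` (enhancers x bins), `meanProfile`, and
#'   `nDropped`.
#' @export
profileMatrix <- function(enhancers, chip, input, flank = 5000L, bin = 100L,
                          pseudo = 0.1) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  nb <- 2L * flank %/% bin
  sl <- seqlengths(chip@seqinfo)
  mid <- midpointBed(enhancers)
  ch <- as.character(seqnames(enhancers))
  ok <- mid - flank >= 0 & mid + flank <= sl[ch]
  kept <- which(ok)
  mat <- matrix(NA_real_, length(kept), nb)
  rownames(mat) <- if (!is.null(mcols(enhancers)$name))
    mcols(enhancers)$name[kept] else as.character(kept)
  for (r in seq_along(kept)) {
    i <- kept[r]
    edges <- mid[i] - flank + (0:nb) * bin
    for (b in seq_len(nb))
      mat[r, b] <- (.trackMean(chip, ch[i], edges[b], edges[b + 1]) + pseudo) /
        (.trackMean(input, ch[i], edges[b], edges[b + 1]) + pseudo)
  }
  list(matrix = mat,
       meanProfile = if (nrow(mat)) colMeans(mat) else rep(NA_real_, nb),
       nDropped = sum(!ok))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided by default (the comparison the study reports). For combined
#' sample sizes up to `exactMax` (default 12) the null distribution of U
#' is obtained by full enumeration of all C(n1+n2, n1) group labelings of
#' the observed (possibly tied) values, so the exact p is correct under
#' ties; above that, the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative "two.sided" (default), "greater" or "less" (shifts
#'   of `x` relative to `y`).
#' @param exactMax largest `n1 + n2` for the enumeration branch.
#' @return List with `U` (statistic for `x`) and `p_value`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))$p_value  # 2/6 by enumeration
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exactMax = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exactMax) {
    combs <- utils::combn(n, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- sqrt(.Machine$double.eps)
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      greater = mean(Us >= U - eps),
      less = mean(Us <= U + eps))
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z <- U - mu
    cc <- 0.5  # continuity correction
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm((abs(z) - cc) / sigma, lower.tail = FALSE),
      greater = stats::pnorm((z - cc) / sigma, lower.tail = FALSE),
      less = stats::pnorm((z + cc) / sigma))
    p <- min(1, p)
  }
  list(U = U, p_value = p)
}

#' Chromatin-state class of enhancers
#'
#' Binary peak-overlap rule: an enhancer is "active"-flagged when it
#' overlaps any active-mark peak (H3K4me1, H3K4me3, H3K27ac) by >= 1 bp,
#' "repressive"-flagged likewise (H3K9me3, H3K27me3); the two flags give
#' the four classes active_only / repressive_only / both / neither.
#' Alternatively `signalThreshold` mode flags a mark when its ChIP/INPUT
#' fold enrichment over the enhancer reaches the threshold.
#'
#' @param enhancers `GRanges`.
#' @param markPeaks named list of peak `GRanges`; must contain all five
#'   marks.
#' @param tracks optional named list of [SignalTrack-class] (plus
#'   "INPUT") for `signalThreshold` mode.
#' @param signalThreshold if non-NULL, use fold >= threshold on tracks
#'   instead of peak overlap.
#' @return Factor with levels active_only, repressive_only, both, neither.
#' @export
stateClass <- function(enhancers, markPeaks, tracks = NULL,
                       signalThreshold = NULL) {
  need <- c(.activeMarks, .repressiveMarks)
  missing <- setdiff(need, names(markPeaks))
  if (length(missing) && is.null(signalThreshold))
    stop("missing mark(s): ", paste(missing, collapse = ", "))
  flagFor <- function(marks) {
    f <- rep(FALSE, length(enhancers))
    for (mk in marks) {
      f <- f | if (is.null(signalThreshold))
        countOverlaps(enhancers, markPeaks[[mk]], ignore.strand = TRUE) > 0
      else
        foldEnrichment(tracks[[mk]], tracks[["INPUT"]], enhancers) >=
          signalThreshold
    }
    f
  }
  act <- flagFor(.activeMarks)
  rep_ <- flagFor(.repressiveMarks)
  cls <- ifelse(act & rep_, "both",
         ifelse(act, "active_only",
         ifelse(rep_, "repressive_only", "neither")))
  factor(cls, levels = c("active_only", "repressive_only", "both", "neither"))
}

#' Open-vs-closed mark comparison table
#'
#' For each mark, the per-enhancer ChIP/INPUT fold enrichment (mean over
#' the call span) is compared between open and closed enhancers with the
#' two-sided rank-sum test.
#'
#' @param enhancers `GRanges`.
#' @param accessibility factor from [classifyAccessibility()].
#' @param tracks named list of [SignalTrack-class] including "INPUT".
#' @param marks marks to compare.
#' @param pseudo passed to [foldEnrichment()].
#' @return `data.frame(mark, n_open, n_closed, mean_fold_open,
#'   mean_fold_closed, U, p_value)`.
#' @export
markComparison <- function(enhancers, accessibility, tracks,
                           marks = c(.activeMarks, .repressiveMarks, "CTCF"),
                           pseudo = 0.1) {
  rows <- lapply(marks, function(mk) {
    fold <- foldEnrichment(tracks[[mk]], tracks[["INPUT"]], enhancers, pseudo)
    xo <- fold[accessibility == "open"]
    xc <- fold[accessibility == "closed"]
    ts <- rankSumTest(xo, xc)
    data.frame(mark = mk, n_open = length(xo), n_closed = length(xc),
               mean_fold_open = mean(xo), mean_fold_closed = mean(xc),
               U = ts$U, p_value = ts$p_value)
  })
  do.call(rbind, rows)
}
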
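# Linking enhancers to complex traits: QTL length filtering and overlap,
# TAD co-membership, and distance-stratified Hi-C contact significance
# between enhancer and gene-promoter bins.

#' Filter out oversized QTL regions
#'
#' Removes QTLs longer than half their chromosome (a region at exactly
#' half the chromosome length is retained); QTLs on chromosomes absent
#' from the assembly are an error. Idempotent.
#'
#' @param qtls `GRanges` with `trait` metadata.
#' @param assembly `Seqinfo`.
#' @return Filtered `GRanges`.
#' @export
filterQtls <- function(qtls, assembly) {
  if (length(qtls) == 0) return(qtls)
  sl <- seqlengths(assembly)
  ch <- as.character(seqnames(qtls))
  if (!all(ch %in% names(sl)))
    stop("QTL on unknown chromosome: ",
         paste(unique(setdiff(ch, names(sl))), collapse = ", "))
  qtls[width(qtls) <= 0.5 * sl[ch]]
}

#' QTL-enhancer overlap summary
#'
#' A QTL region counts when it overlaps at least one enhancer by >= 1 bp.
#' Non-redundant regions are exact-coordinate deduplicates by default
#' (duplicate records from different trait associations collapse to one
#' region but contribute all their traits); `mergeOverlapping = TRUE`
#' merges overlapping regions instead.
#'
#' @param qtls filtered `GRanges` with `trait` metadata.
#' @param enhancers `GRanges`.
#' @param mergeOverlapping alternative non-redundancy rule.
#' @return List with `perQtl` (list of enhancer indices per QTL record),
#'   `nNonredundantQtls`, `nTraits`.
#' @export
qtlEnhancerOverlap <- function(qtls, enhancers, mergeOverlapping = FALSE) {
  hit <- findOverlaps(qtls, enhancers, ignore.strand = TRUE)
  perQtl <- split(S4Vectors::subjectHits(hit),
                  factor(S4Vectors::queryHits(hit), levels = seq_along(qtls)))
  counted <- which(lengths(perQtl) > 0)
  if (length(counted) == 0)
    return(list(perQtl = perQtl, nNonredundantQtls = 0L, nTraits = 0L))
  sub <- qtls[counted]
  nNR <- if (mergeOverlapping) length(reduce(granges(sub), ignore.strand = TRUE))
  else length(unique(paste(as.character(seqnames(sub)), start(sub), end(sub))))
  list(perQtl = perQtl,
       nNonredundantQtls = as.integer(nNR),
       nTraits = length(unique(mcols(sub)$trait)))
}

#' TAD co-membership of two intervals
#'
#' TRUE iff a single TAD contains the midpoints of both intervals. TADs
#' must be non-overlapping per chromosome (overlapping TADs are corrupt
#' input); intervals on different chromosomes are never co-resident.
#'
#' @param a,b single-interval `GRanges` (vectorized element-wise).
#' @param tads `GRanges` of TADs.
#' @return Logical vector.
#' @export
sameTad <- function(a, b, tads) {
  red <- reduce(granges(tads), ignore.strand = TRUE, min.gapwidth = 0L)
  if (length(red) != length(tads))
    stop("overlapping TADs (corrupt input)")
  # suppressed warning: anchors on chromosomes without TADs are simply
  # not co-resident
  ta <- suppressWarnings(findOverlaps(midpointRanges(a), tads,
                                      ignore.strand = TRUE, select = "first"))
  tb <- suppressWarnings(findOverlaps(midpointRanges(b), tads,
                                      ignore.strand = TRUE, select = "first"))
  !is.na(ta) & !is.na(tb) & ta == tb
}

#' Distance-stratified Hi-C contact significance
#'
#' Observed contact is the matrix entry at the bins containing the two
#' anchor midpoints; expected is the mean of all entries of that
#' chromosome's matrix at the same bin distance; the p-value is the
#' Poisson upper tail `P(X >= observed)` at the expected mean. The study
#' leaves "significant Hi-C contact" undefined; this distance-stratified
#' Poisson test is the simplest defensible expected model and is
#' replaceable.
#'
#' @param m a [ContactMatrix-class].
#' @param a,b single-interval `GRanges` on the same chromosome of `m`.
#' @return List with `observed`, `expected`, `p_value`.
#' @export
contactSignificance <- function(m, a, b) {
  ch <- as.character(seqnames(a))[1]
  if (ch != as.character(seqnames(b))[1])
    stop("anchors must be on the same chromosome")
  mat <- m@matrices[[ch]]
  if (is.null(mat)) stop("no contact matrix for ", ch)
  i <- midpointBed(a)[1] %/% m@resolution + 1L
  j <- midpointBed(b)[1] %/% m@resolution + 1L
  nb <- nrow(mat)
  if (i < 1 || j < 1 || i > nb || j > nb)
    stop("anchor bin out of matrix range")
  obs <- mat[i, j]
  d <- abs(i - j)
  idx <- which(abs(row(mat) - col(mat)) == d)
  expd <- mean(mat[idx])
  p <- stats::ppois(ceiling(obs) - 1, lambda = expd, lower.tail = FALSE)
  list(observed = obs, expected = expd, p_value = p)
}

#' Link enhancers to traits through QTLs, TADs and Hi-C contact
#'
#' For every enhancer overlapping a (filtered) QTL by >= 1 bp and every
#' gene whose span overlaps that QTL, emits a candidate trait link with
#' TAD co-membership flag and contact significance between the enhancer
#' bin and the gene's TSS bin (the promoter is the biological anchor of
#' the regulatory claim). The link is flagged a candidate iff the pair
#' shares a TAD and the contact p-value is below `alpha`.
#'
#' @param enhancers `GRanges` with a `name` column.
#' @param qtls filtered `GRanges` with `trait` metadata.
#' @param genes `GRanges` with `gene_id` and `tss` metadata.
#' @param tads `GRanges` of TADs.
#' @param m a [ContactMatrix-class].
#' @param alpha contact significance level (default 0.05).
#' @return `data.frame` with one row per (enhancer, QTL, gene) triple:
#'   enhancer, trait, gene, same_tad, observed, expected, contact_p,
#'   candidate.
#' @export
linkEnhancers <- function(enhancers, qtls, genes, tads, m, alpha = 0.05) {
  if (length(reduce(granges(tads), ignore.strand = TRUE,
                    min.gapwidth = 0L)) != length(tads))
    stop("overlapping TADs (corrupt input)")
  # precomputed per-chromosome: TAD index per bin anchor, distance means
  distMean <- lapply(m@matrices, function(mat) {
    d <- abs(row(mat) - col(mat))
    as.numeric(tapply(mat, d, mean))  # index = distance + 1
  })
  enhTad <- findOverlaps(midpointRanges(enhancers), tads,
                         ignore.strand = TRUE, select = "first")
  tssAnchors <- GRanges(seqnames(genes), IRanges(mcols(genes)$tss + 1L,
                                                 width = 1L))
  geneTad <- findOverlaps(tssAnchors, tads, ignore.strand = TRUE,
                          select = "first")
  eq <- findOverlaps(enhancers, qtls, ignore.strand = TRUE)
  gq <- findOverlaps(genes, qtls, ignore.strand = TRUE)
  gqByQtl <- split(S4Vectors::queryHits(gq),
                   factor(S4Vectors::subjectHits(gq), levels = seq_along(qtls)))
  rows <- list()
  for (k in seq_along(eq)) {
    ei <- S4Vectors::queryHits(eq)[k]
    qi <- S4Vectors::subjectHits(eq)[k]
    for (gi in gqByQtl[[qi]]) {
      ch <- as.character(seqnames(enhancers))[ei]
      if (ch != as.character(seqnames(genes))[gi]) next
      st <- !is.na(enhTad[ei]) && !is.na(geneTad[gi]) &&
        enhTad[ei] == geneTad[gi]
      mat <- m@matrices[[ch]]
      if (is.null(mat)) stop("no contact matrix for ", ch)
      i <- midpointBed(enhancers[ei]) %/% m@resolution + 1L
      j <- mcols(genes)$tss[gi] %/% m@resolution + 1L
      if (i < 1 || j < 1 || i > nrow(mat) || j > nrow(mat))
        stop("anchor bin out of matrix range")
      obs <- mat[i, j]
      expd <- distMean[[ch]][abs(i - j) + 1L]
      p <- stats::ppois(ceiling(obs) - 1, lambda = expd, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        enhancer = if (!is.null(mcols(enhancers)$name))
          mcols(enhancers)$name[ei] else as.character(ei),
        trait = mcols(qtls)$trait[qi],
        gene = mcols(genes)$gene_id[gi],
        same_tad = st,
        observed = obs, expected = expd, contact_p = p,
        candidate = st && p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(enhancer = character(), trait = character(),
                      gene = character(), same_tad = logical(),
                      observed = numeric(), expected = numeric(),
                      contact_p = numeric(), candidate = logical()))
  do.call(rbind, rows)
}
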
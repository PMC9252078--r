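# Seeded synthetic-study generator. Every simulator is a pure function of
# (config, seed): it derives an isolated RNG stream from the user seed and
# the operation name, so adding or reordering simulators never perturbs the
# draws of another, and restores the caller's RNG state on exit.

.opSeed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# non-overlapping placement of segments of given lengths on [0, L):
# stick-breaking over the free space keeps order statistics uniform
.placeNonOverlapping <- function(lens, L) {
  total <- sum(lens)
  if (total > L) stop("infeasible packing: requested segments exceed chromosome")
  n <- length(lens)
  if (n == 0) return(integer())
  free <- L - total
  cuts <- sort(round(stats::runif(n, 0, free)))
  cuts + cumsum(c(0, lens[-n]))
}

#' Simulate a toy genome with annotations and planted enhancers
#'
#' Generates the assembly, a repeat annotation (with LINE/SINE/LTR/DNA
#' transposable-element subclasses), non-overlapping gene models with TSS,
#' exon, first-intron and UTR structure, a TAD segmentation, and the
#' planted-enhancer ground truth. Planted enhancers are aligned to the
#' `enhancerLength` analysis grid, separated by at least two grid bins,
#' and placed inside repeats for `enhancerRepeatFraction` of them. A small
#' number of enhancers are linked to a same-TAD gene promoter (the Hi-C
#' simulator boosts those contacts). Deterministic given `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return A list: `assembly` (Seqinfo), `repeats` (GRanges, TE class in
#'   `name`), `geneModel` (genes/exons/introns/utr5/utr3 GRanges), `tads`
#'   (GRanges), `truth` (GRanges with `activity`, `open_chromatin`,
#'   per-mark flags and `linked_gene`), and `config`.
#' @export
simulateGenome <- function(config) {
  validObject(config)
  .withSeed(.opSeed(config@seed, "simulate_genome"), {
    L <- as.integer(config@chromLength)
    chroms <- paste0("chr", seq_len(config@nChroms))
    assembly <- genomeAssembly(chroms, rep(L, config@nChroms))

    ## repeats: segments drawn until the per-chromosome target is reached
    repList <- list()
    for (ch in chroms) {
      target <- config@repeatFraction * L
      if (target > 0) {
        lens <- integer()
        while (sum(lens) < target)
          lens <- c(lens, as.integer(round(stats::runif(50, 500, 3000))))
        # trim to within 2% of target
        keep <- which(cumsum(lens) <= target * 1.02)
        lens <- lens[keep]
        starts <- .placeNonOverlapping(lens, L)
        cls <- sample(c(names(config@teClassWeights), "Unclassified"),
                      length(lens), replace = TRUE,
                      prob = c(config@teClassWeights,
                               max(0, 1 - sum(config@teClassWeights))))
        gr <- GRanges(ch, IRanges(starts + 1L, width = lens))
        mcols(gr)$name <- cls
        repList[[ch]] <- gr
      }
    }
    repeats <- if (length(repList)) {
      out <- suppressWarnings(do.call(c, unname(repList)))
      seqinfo(out) <- assembly[seqlevels(out)]
      out
    } else GRanges()

    ## gene models: non-overlapping spans, 3 exons / 2 introns, UTRs
    perChrom <- ceiling(config@nGenes / config@nChroms)
    geneRows <- list(); exonRows <- list(); intronRows <- list()
    utr5Rows <- list(); utr3Rows <- list()
    gid <- 0L
    for (ch in chroms) {
      n <- min(perChrom, config@nGenes - gid)
      if (n <= 0) break
      lens <- as.integer(round(stats::runif(n, 3000, 12000)))
      starts <- .placeNonOverlapping(lens, L)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      for (k in seq_len(n)) {
        gid <- gid + 1L
        id <- sprintf("gene%04d", gid)
        s0 <- starts[k]; gl <- lens[k]
        # fractional layout exon/intron/exon/intron/exon = 10/35/10/35/10
        b <- s0 + round(cumsum(c(0, 0.10, 0.35, 0.10, 0.35, 0.10)) * gl)
        ex <- rbind(c(b[1], b[2]), c(b[3], b[4]), c(b[5], b[6]))
        intr <- rbind(c(b[2], b[3]), c(b[4], b[5]))
        str <- strands[k]
        geneRows[[id]] <- data.frame(c1 = ch, c2 = s0, c3 = s0 + gl, c4 = str)
        exonRows[[id]] <- data.frame(c1 = ch, c2 = ex[, 1], c3 = ex[, 2], c4 = str, c5 = id)
        # intron rank 1 = adjacent to the TSS (transcription order)
        rk <- if (str == "+") 1:2 else 2:1
        intronRows[[id]] <- data.frame(c1 = ch, c2 = intr[, 1], c3 = intr[, 2], c4 = str, c5 = id, c6 = rk)
        # 5'UTR = first 100 bp transcribed; 3'UTR = last 200 bp
        if (str == "+") {
          utr5Rows[[id]] <- data.frame(c1 = ch, c2 = b[1], c3 = b[1] + 100, c4 = str, c5 = id)
          utr3Rows[[id]] <- data.frame(c1 = ch, c2 = b[6] - 200, c3 = b[6], c4 = str, c5 = id)
        } else {
          utr5Rows[[id]] <- data.frame(c1 = ch, c2 = b[6] - 100, c3 = b[6], c4 = str, c5 = id)
          utr3Rows[[id]] <- data.frame(c1 = ch, c2 = b[1], c3 = b[1] + 200, c4 = str, c5 = id)
        }
      }
    }
    asGr <- function(rows, withRank = FALSE) {
      df <- do.call(rbind, rows)
      gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), strand = df[[4]],
                    seqinfo = assembly)
      if (ncol(df) >= 5) mcols(gr)$gene_id <- df[[5]]
      if (withRank) mcols(gr)$rank <- df[[6]]
      gr
    }
    genes <- asGr(lapply(names(geneRows), function(id)
      cbind(geneRows[[id]], c5 = id)))
    mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "-",
                               bedEnd(genes) - 1L, bedStart(genes))
    geneModel <- list(genes = genes, exons = asGr(exonRows),
                      introns = asGr(intronRows, withRank = TRUE),
                      utr5 = asGr(utr5Rows), utr3 = asGr(utr3Rows))

    ## TADs: consecutive blocks of 40 kb bins, 8-16 bins each
    tadList <- list()
    for (ch in chroms) {
      nb <- L %/% 40000L
      b <- 0L; bounds <- 0L
      while (b < nb) {
        b <- min(nb, b + sample(8:16, 1))
        bounds <- c(bounds, b)
      }
      tadList[[ch]] <- GRanges(ch, IRanges(head(bounds, -1) * 40000L + 1L,
                                           bounds[-1] * 40000L),
                               seqinfo = assembly)
    }
    tads <- suppressWarnings(do.call(c, unname(tadList)))
    mcols(tads)$name <- sprintf("tad%03d", seq_along(tads))

    ## planted enhancers on the analysis grid
    w <- config@enhancerLength
    grid <- binGenome(assembly, w)
    grid <- grid[width(grid) == w]
    inRep <- countOverlaps(grid, repeats, type = "within",
                           ignore.strand = TRUE) > 0
    nRep <- if (length(repeats) && any(inRep))
      round(config@nEnhancers * config@enhancerRepeatFraction) else 0L
    pickSeparated <- function(cand, n) {
      picked <- integer()
      cand <- sample(cand)
      for (i in cand) {
        if (length(picked) == n) break
        if (!any(abs(i - picked) <= 2)) picked <- c(picked, i)
      }
      if (length(picked) < n)
        stop("infeasible packing: not enough candidate bins for enhancers")
      picked
    }
    idxRep <- pickSeparated(which(inRep), nRep)
    idxNon <- pickSeparated(setdiff(which(!inRep),
                                    unlist(lapply(idxRep, function(i) i + (-2:2)))),
                            config@nEnhancers - nRep)
    idx <- sort(c(idxRep, idxNon))
    truth <- grid[idx]
    ne <- length(truth)
    mcols(truth)$name <- sprintf("enh%03d", seq_len(ne))
    mcols(truth)$activity <- stats::runif(ne, config@activityRange[1],
                                          config@activityRange[2])
    mcols(truth)$in_repeat <- idx %in% idxRep
    mcols(truth)$open_chromatin <- stats::runif(ne) < config@openFraction
    markP <- c(H3K4me1 = 0.30, H3K4me3 = 0.15, H3K27ac = 0.30,
               H3K9me3 = 0.45, H3K27me3 = 0.35, CTCF = 0.30)
    for (mk in names(markP))
      mcols(truth)[[mk]] <- stats::runif(ne) < markP[[mk]]

    ## link a few enhancers to a same-TAD promoter >= 2 Hi-C bins away
    mcols(truth)$linked_gene <- NA_character_
    tadHit <- findOverlaps(midpointRanges(truth), tads, ignore.strand = TRUE)
    tssPos <- GRanges(seqnames(genes), IRanges(mcols(genes)$tss + 1L, width = 1L))
    geneTad <- findOverlaps(tssPos, tads, ignore.strand = TRUE)
    nLinks <- min(3L, ne)
    made <- 0L
    for (i in sample(seq_len(ne))) {
      if (made == nLinks) break
      td <- S4Vectors::subjectHits(tadHit)[match(i, S4Vectors::queryHits(tadHit))]
      if (is.na(td)) next
      cand <- S4Vectors::queryHits(geneTad)[S4Vectors::subjectHits(geneTad) == td]
      if (!length(cand)) next
      dist <- abs(mcols(genes)$tss[cand] - midpointBed(truth)[i])
      cand <- cand[dist >= 80000]  # >= 2 bins at 40 kb
      if (!length(cand)) next
      mcols(truth)$linked_gene[i] <- mcols(genes)$gene_id[cand[1]]
      made <- made + 1L
    }

    list(assembly = assembly, repeats = repeats, geneModel = geneModel,
         tads = tads, truth = truth, config = config)
  })
}

#' Simulate a STARR-seq fragment library
#'
#' The input-plasmid library stands for the cloned fragment pool:
#' fragment midpoints are uniform over the genome and lengths are
#' Normal(`fragLenMean`, `fragLenSd`) clipped to [200, 1200], strand
#' uniform. The cDNA library is drawn from the candidate fragments of the
#' same replicate's plasmid pool, each accepted with probability
#' proportional to the activity of the planted enhancer containing its
#' midpoint (1 outside enhancers) — transcribed molecules are physically
#' a weighted resample of the transfected pool, so the input library's
#' window fraction is the exact null sampling probability for the cDNA
#' counts. Duplicates in the cDNA library are possible by construction.
#'
#' @param sim output of [simulateGenome()].
#' @param library "input" or "cdna".
#' @param n number of fragments (defaults to the config's library size).
#' @param seed stream seed (defaults to the config seed; library,
#'   replicate and cell line identity are mixed in, so replicates differ).
#' @param replicate,cellLine provenance labels.
#' @param pool for "cdna": the matching input [FragmentLibrary-class] to
#'   resample from; when NULL it is regenerated deterministically from the
#'   same (seed, replicate, cellLine), so a standalone cDNA library is
#'   consistent with its standalone input counterpart.
#' @return A [FragmentLibrary-class].
#' @export
simulateFragments <- function(sim, library = c("input", "cdna"), n = NULL,
                              seed = NULL, replicate = "rep1",
                              cellLine = "cellA", pool = NULL) {
  library <- match.arg(library)
  cfg <- sim$config
  if (is.null(n))
    n <- if (library == "input") cfg@nInputFrags else cfg@nCdnaFrags
  if (is.null(seed)) seed <- cfg@seed
  op <- paste("simulate_fragments", library, replicate, cellLine)
  if (library == "cdna") {
    if (is.null(pool))
      pool <- simulateFragments(sim, "input", seed = seed,
                                replicate = replicate, cellLine = cellLine)
    cand <- fragments(pool)
    truth <- sim$truth
    wgt <- rep(1, length(cand))
    if (length(truth)) {
      hit <- findOverlaps(midpointRanges(cand), truth, ignore.strand = TRUE)
      wgt[S4Vectors::queryHits(hit)] <-
        mcols(truth)$activity[S4Vectors::subjectHits(hit)]
    }
    return(.withSeed(.opSeed(seed, op), {
      idx <- sample.int(length(cand), n, replace = TRUE, prob = wgt)
      fragmentLibrary(cand[idx], label = "cdna", replicate = replicate,
                      cellLine = cellLine)
    }))
  }
  sl <- seqlengths(sim$assembly)
  offs <- cumsum(c(0, as.numeric(sl)))
  G <- offs[length(offs)]
  .withSeed(.opSeed(seed, op), {
    midG <- floor(stats::runif(n, 0, G))
    lens <- as.integer(round(pmin(1200, pmax(200,
              stats::rnorm(n, cfg@fragLenMean, cfg@fragLenSd)))))
    ci <- findInterval(midG, offs, rightmost.closed = FALSE)
    chrom <- names(sl)[ci]
    pos <- midG - offs[ci]
    s0 <- pos - lens %/% 2L
    s0 <- pmax(0, pmin(s0, as.numeric(sl[ci]) - lens))
    gr <- GRanges(chrom, IRanges(s0 + 1L, width = lens),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  seqinfo = sim$assembly)
    fragmentLibrary(gr, label = "input", replicate = replicate,
                    cellLine = cellLine)
  })
}

.knownMarks <- c("ATAC", "H3K4me1", "H3K4me3", "H3K27ac", "H3K9me3",
                 "H3K27me3", "CTCF", "INPUT")

#' Simulate a chromatin signal track with planted peaks
#'
#' Baseline signal is noise around 1.0; where the ground truth carries the
#' mark (or `open_chromatin` for "ATAC"), a peak spanning the enhancer
#' plus 300 bp flanks is planted with fold >= 3 over the matched "INPUT"
#' track (which has no peaks).
#'
#' @param sim output of [simulateGenome()].
#' @param mark one of ATAC, H3K4me1, H3K4me3, H3K27ac, H3K9me3, H3K27me3,
#'   CTCF, INPUT.
#' @param seed stream seed (defaults to the config seed).
#' @param binWidth track bin width in bp.
#' @return List with `peaks` (GRanges, empty for INPUT) and `track`
#'   ([SignalTrack-class]).
#' @export
simulateTracks <- function(sim, mark, seed = NULL, binWidth = 100L) {
  if (!mark %in% .knownMarks)
    stop("unknown mark '", mark, "'; known: ", paste(.knownMarks, collapse = ", "))
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg@seed
  sl <- seqlengths(sim$assembly)
  .withSeed(.opSeed(seed, paste("simulate_tracks", mark)), {
    vals <- lapply(seqlevels(sim$assembly), function(ch)
      pmax(0, stats::rnorm(ceiling(sl[[ch]] / binWidth), 1, 0.15)))
    names(vals) <- seqlevels(sim$assembly)
    peaks <- GRanges(seqinfo = sim$assembly)
    if (mark != "INPUT" && length(sim$truth)) {
      flag <- if (mark == "ATAC") mcols(sim$truth)$open_chromatin
              else mcols(sim$truth)[[mark]]
      sel <- sim$truth[flag]
      if (length(sel)) {
        peaks <- GRanges(seqnames(sel),
                         IRanges(pmax(1L, start(sel) - 300L),
                                 pmin(sl[as.character(seqnames(sel))],
                                      end(sel) + 300L)),
                         seqinfo = sim$assembly)
        mcols(peaks)$name <- mcols(sel)$name
        fold <- stats::runif(length(peaks), 3.5, 6)
        for (k in seq_along(peaks)) {
          ch <- as.character(seqnames(peaks))[k]
          b0 <- (start(peaks)[k] - 1L) %/% binWidth + 1L
          b1 <- (end(peaks)[k] - 1L) %/% binWidth + 1L
          vals[[ch]][b0:b1] <- vals[[ch]][b0:b1] * fold[k]
        }
      }
    }
    list(peaks = peaks,
         track = signalTrack(vals, binWidth, sim$assembly, mark))
  })
}

#' Simulate Hi-C contact matrices with TAD structure and planted links
#'
#' Expected contact between bins at distance `d` is `C / (1 + d)`, doubled
#' (`tadBoost`) within a TAD and multiplied by `beta` for planted
#' enhancer-promoter pairs; observed counts are Poisson around the
#' expectation, symmetric by construction.
#'
#' @param sim output of [simulateGenome()].
#' @param resolution bin size in bp; must give >= 2 bins per chromosome.
#' @param seed stream seed (defaults to the config seed).
#' @param C contact scale at distance 0.
#' @param beta boost factor for planted enhancer-gene links.
#' @param tadBoost intra-TAD contact elevation (1 = no TAD structure).
#' @param links optional data.frame(chrom, binA, binB) of 1-based bin pairs
#'   to boost; defaults to the ground truth's `linked_gene` pairs
#'   (enhancer midpoint bin vs gene TSS bin).
#' @return List with `contacts` ([ContactMatrix-class]), `tads` (GRanges),
#'   and `links` (the boosted pairs actually used).
#' @export
simulateHic <- function(sim, resolution = 40000L, seed = NULL, C = 100,
                        beta = 5, tadBoost = 2, links = NULL) {
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg@seed
  sl <- seqlengths(sim$assembly)
  if (any(ceiling(sl / resolution) < 2))
    stop("resolution must give at least 2 bins per chromosome")
  if (is.null(links)) {
    truth <- sim$truth
    genes <- sim$geneModel$genes
    li <- which(!is.na(mcols(truth)$linked_gene))
    links <- data.frame(
      chrom = as.character(seqnames(truth))[li],
      binA = midpointBed(truth)[li] %/% resolution + 1L,
      binB = mcols(genes)$tss[match(mcols(truth)$linked_gene[li],
                                    mcols(genes)$gene_id)] %/% resolution + 1L,
      enhancer = mcols(truth)$name[li],
      gene = mcols(truth)$linked_gene[li],
      stringsAsFactors = FALSE)
  }
  .withSeed(.opSeed(seed, "simulate_hic"), {
    mats <- list()
    for (ch in seqlevels(sim$assembly)) {
      nb <- as.integer(ceiling(sl[[ch]] / resolution))
      d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
      lambda <- C / (1 + d)
      # intra-TAD elevation: bins whose midpoints share a TAD
      tadIdx <- rep(NA_integer_, nb)
      tds <- sim$tads[seqnames(sim$tads) == ch]
      binMid <- (seq_len(nb) - 1) * resolution + resolution / 2
      for (t in seq_along(tds))
        tadIdx[binMid >= start(tds)[t] - 1 & binMid < end(tds)[t]] <- t
      same <- outer(tadIdx, tadIdx, function(a, b)
        !is.na(a) & !is.na(b) & a == b)
      lambda[same] <- lambda[same] * tadBoost
      for (k in which(links$chrom == ch)) {
        i <- links$binA[k]; j <- links$binB[k]
        if (i >= 1 && j >= 1 && i <= nb && j <= nb) {
          lambda[i, j] <- lambda[i, j] * beta
          lambda[j, i] <- lambda[i, j]
        }
      }
      m <- matrix(0, nb, nb)
      ut <- upper.tri(m, diag = TRUE)
      m[ut] <- stats::rpois(sum(ut), lambda[ut])
      m <- m + t(m) - diag(diag(m), nb)
      mats[[ch]] <- m
    }
    list(contacts = contactMatrix(mats, resolution, sim$assembly),
         tads = sim$tads, links = links)
  })
}

#' Simulate a gene expression table
#'
#' A configured fraction of genes is exactly 0 FPKM (silent); the rest are
#' log-normal.
#'
#' @param sim output of [simulateGenome()].
#' @param seed stream seed (defaults to the config seed).
#' @param silentFraction overrides the config's silent fraction.
#' @return Named numeric vector of FPKM by gene id.
#' @export
simulateExpression <- function(sim, seed = NULL, silentFraction = NULL) {
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg@seed
  if (is.null(silentFraction)) silentFraction <- cfg@silentFraction
  ids <- mcols(sim$geneModel$genes)$gene_id
  .withSeed(.opSeed(seed, "simulate_expression"), {
    n <- length(ids)
    fpkm <- stats::rlnorm(n, meanlog = 0.5, sdlog = 1.5)
    silent <- stats::runif(n) < silentFraction
    fpkm[silent] <- 0
    stats::setNames(round(fpkm, 4), ids)
  })
}

#' Simulate QTL regions
#'
#' Plants one QTL over each linked enhancer-gene pair (so the trait-linkage
#' stage has true positives to find) plus random background QTLs with
#' trait labels, including a few oversized regions longer than half a
#' chromosome to exercise the QTL length filter.
#'
#' @param sim output of [simulateGenome()].
#' @param seed stream seed (defaults to the config seed).
#' @param nBackground number of background QTLs.
#' @return `GRanges` with `trait` and `source` metadata.
#' @export
simulateQtls <- function(sim, seed = NULL, nBackground = 30L) {
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg@seed
  sl <- seqlengths(sim$assembly)
  truth <- sim$truth
  genes <- sim$geneModel$genes
  .withSeed(.opSeed(seed, "simulate_qtls"), {
    rows <- list()
    li <- which(!is.na(mcols(truth)$linked_gene))
    for (k in seq_along(li)) {
      i <- li[k]
      g <- genes[match(mcols(truth)$linked_gene[i], mcols(genes)$gene_id)]
      ch <- as.character(seqnames(truth))[i]
      lo <- max(0, min(bedStart(truth)[i], bedStart(g)) - 10000)
      hi <- min(sl[[ch]], max(bedEnd(truth)[i], bedEnd(g)) + 10000)
      rows[[length(rows) + 1L]] <-
        data.frame(c1 = ch, c2 = lo, c3 = hi, c4 = sprintf("planted_trait_%d", k), c5 = "planted")
    }
    for (k in seq_len(nBackground)) {
      ch <- sample(names(sl), 1)
      len <- if (k <= 2) round(0.6 * sl[[ch]])  # oversized, must be filtered
             else round(stats::runif(1, 5e4, 4e5))
      lo <- floor(stats::runif(1, 0, sl[[ch]] - len))
      rows[[length(rows) + 1L]] <-
        data.frame(c1 = ch, c2 = lo, c3 = lo + len,
                   c4 = sprintf("trait_%02d", sample(15, 1)), c5 = "background")
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                  seqinfo = sim$assembly)
    mcols(gr)$trait <- df[[4]]
    mcols(gr)$source <- df[[5]]
    gr
  })
}

#' Simulate a complete STARR-seq study
#'
#' Orchestrates the individual simulators into the full input bundle of
#' the pipeline: genome and annotations, input/cDNA fragment libraries for
#' each cell line and replicate, chromatin tracks and peaks for every
#' mark, expression, QTLs, TADs and Hi-C contacts.
#'
#' @param config a [SimConfig-class].
#' @param cellLines,replicates character vectors of identifiers.
#' @param marks marks to simulate tracks for.
#' @return A list with elements `genome`, `libraries` (nested
#'   `[[cellLine]][[replicate]][[label]]`), `tracks`, `peaks`, `expression`,
#'   `qtls`, `hic`.
#' @export
simulateStudy <- function(config, cellLines = c("cellA", "cellB"),
                          replicates = c("rep1", "rep2"),
                          marks = .knownMarks) {
  genome <- simulateGenome(config)
  libraries <- list()
  for (clI in seq_along(cellLines)) for (rpI in seq_along(replicates)) {
    cl <- cellLines[clI]; rp <- replicates[rpI]
    inp <- simulateFragments(genome, "input", replicate = rp, cellLine = cl)
    libraries[[cl]][[rp]] <- list(
      input = inp,
      cdna = simulateFragments(genome, "cdna", replicate = rp,
                               cellLine = cl, pool = inp))
  }
  tracks <- list(); peaks <- list()
  for (mk in marks) {
    tr <- simulateTracks(genome, mk)
    tracks[[mk]] <- tr$track
    if (mk != "INPUT") peaks[[mk]] <- tr$peaks
  }
  list(genome = genome, libraries = libraries, tracks = tracks,
       peaks = peaks, expression = simulateExpression(genome),
       qtls = simulateQtls(genome), hic = simulateHic(genome))
}

#' Write a simulated study to disk
#'
#' Emits the study as the plain-text formats the pipeline consumes:
#' chrom.sizes, fragment BED6 per library, repeats/truth/TADs/peaks BED,
#' genes GTF, expression TSV, QTL table, and dense contact matrices.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- study$genome
  writeChromSizes(g$assembly, file.path(dir, "genome.chrom.sizes"))
  writeBed(g$repeats, file.path(dir, "repeats.bed"))
  writeBed(g$truth, file.path(dir, "truth_enhancers.bed"))
  writeBed(g$tads, file.path(dir, "tads.bed"))
  writeGtfGenes(g$geneModel, file.path(dir, "genes.gtf"))
  writeExpression(study$expression, file.path(dir, "expression.tsv"))
  writeQtls(study$qtls, file.path(dir, "qtls.tsv"))
  for (cl in names(study$libraries))
    for (rp in names(study$libraries[[cl]]))
      for (lab in names(study$libraries[[cl]][[rp]]))
        writeBed(fragments(study$libraries[[cl]][[rp]][[lab]]),
                 file.path(dir, sprintf("%s_%s_%s.bed", cl, rp, lab)))
  for (mk in names(study$tracks))
    writeBedGraph(study$tracks[[mk]],
                  file.path(dir, paste0("track_", mk, ".bedgraph")))
  for (mk in names(study$peaks))
    writeBed(study$peaks[[mk]], file.path(dir, paste0("peaks_", mk, ".bed")))
  writeContactMatrix(study$hic$contacts, dir)
  invisible(dir)
}
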
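#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps reduce tileGenome sort.GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<-
#' @importFrom utils head combn write.table
#' @importFrom stats setNames
NULL

#' Configuration of a synthetic STARR-seq study
#'
#' Holds every tunable of the synthetic-study generator: genome geometry,
#' annotation density, planted-enhancer regime, and sequencing-library
#' depth. Defaults emulate the real study's libraries scaled down ~1000x:
#' two chromosomes of 2.5 Mb (preserving the study's per-600 bp-bin input
#' fragment depth of ~12 at 1e5 fragments per library), median fragment
#' length 600 bp (Normal(600, 100) clipped to [200, 1200]), 20 planted
#' enhancers of 600 bp with activity fold-changes drawn from [3, 6], and a
#' repeat-rich genome (45% repetitive) dominated by LINEs.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength length of each chromosome in bp.
#' @slot nGenes total number of genes.
#' @slot repeatFraction target fraction of the genome in repeats.
#' @slot teClassWeights named numeric over LINE/SINE/LTR/DNA summing to <= 1;
#'   the remainder of the repeat space is non-TE repeat.
#' @slot nEnhancers number of planted enhancers.
#' @slot enhancerLength planted enhancer width in bp (grid-aligned to the
#'   analysis bin width).
#' @slot activityRange two-element numeric, min/max activity fold multiplier.
#' @slot enhancerRepeatFraction fraction of planted enhancers placed inside
#'   repeats.
#' @slot nInputFrags,nCdnaFrags fragments per library.
#' @slot fragLenMean,fragLenSd fragment length distribution in bp.
#' @slot silentFraction fraction of genes with FPKM exactly 0.
#' @slot openFraction fraction of enhancers overlapping an accessible
#'   (ATAC) region.
#' @slot seed integer seed; every simulator derives its stream from
#'   (seed, operation name).
#' @export
setClass("SimConfig",
  representation(
    nChroms = "integer", chromLength = "numeric", nGenes = "integer",
    repeatFraction = "numeric", teClassWeights = "numeric",
    nEnhancers = "integer", enhancerLength = "integer",
    activityRange = "numeric", enhancerRepeatFraction = "numeric",
    nInputFrags = "integer", nCdnaFrags = "integer",
    fragLenMean = "numeric", fragLenSd = "numeric",
    silentFraction = "numeric", openFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@repeatFraction, object@silentFraction, object@openFraction,
          object@enhancerRepeatFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(object@teClassWeights < 0) || sum(object@teClassWeights) > 1 + 1e-9)
    msg <- c(msg, "teClassWeights must be non-negative and sum to <= 1")
  if (!identical(sort(names(object@teClassWeights)),
                 sort(c("LINE", "SINE", "LTR", "DNA"))))
    msg <- c(msg, "teClassWeights must be named LINE, SINE, LTR, DNA")
  if (length(object@activityRange) != 2L ||
      any(object@activityRange < 1))
    msg <- c(msg, "activityRange must be two multipliers >= 1")
  cnt <- c(object@nChroms, object@nGenes, object@nEnhancers,
           object@enhancerLength, object@nInputFrags, object@nCdnaFrags)
  if (any(cnt <= 0)) msg <- c(msg, "counts and lengths must be > 0")
  if (object@chromLength <= 0) msg <- c(msg, "chromLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' @param nChroms,chromLength,nGenes,repeatFraction,teClassWeights,nEnhancers,enhancerLength,activityRange,enhancerRepeatFraction,nInputFrags,nCdnaFrags,fragLenMean,fragLenSd,silentFraction,openFraction,seed
#'   see the slot documentation in [SimConfig-class].
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(nChroms = 2L, chromLength = 2.5e6, nGenes = 200L,
                      repeatFraction = 0.45,
                      teClassWeights = c(LINE = 0.5, SINE = 0.15,
                                         LTR = 0.1, DNA = 0.05),
                      nEnhancers = 20L, enhancerLength = 600L,
                      activityRange = c(3, 6),
                      enhancerRepeatFraction = 0.8,
                      nInputFrags = 1e5L, nCdnaFrags = 1e5L,
                      fragLenMean = 600, fragLenSd = 100,
                      silentFraction = 0.3, openFraction = 0.2,
                      seed = 1L) {
  new("SimConfig",
      nChroms = as.integer(nChroms), chromLength = as.numeric(chromLength),
      nGenes = as.integer(nGenes), repeatFraction = repeatFraction,
      teClassWeights = teClassWeights, nEnhancers = as.integer(nEnhancers),
      enhancerLength = as.integer(enhancerLength),
      activityRange = as.numeric(activityRange),
      enhancerRepeatFraction = enhancerRepeatFraction,
      nInputFrags = as.integer(nInputFrags),
      nCdnaFrags = as.integer(nCdnaFrags),
      fragLenMean = fragLenMean, fragLenSd = fragLenSd,
      silentFraction = silentFraction, openFraction = openFraction,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nChroms, " chrom x ",
      format(object@chromLength, big.mark = ","), " bp, ",
      object@nGenes, " genes, ", object@nEnhancers,
      " planted enhancers (activity ",
      object@activityRange[1], "-", object@activityRange[2], "), ",
      object@nInputFrags, "/", object@nCdnaFrags,
      " input/cDNA fragments, seed ", object@seed, "\n", sep = "")
})

#' Deduplicated STARR-seq fragment library
#'
#' A set of sequenced-fragment intervals (with strand) for one library of
#' one replicate, together with the unique-fragment total used as the
#' denominator of all per-window rates. `label` distinguishes the
#' pre-transfection input-plasmid library (the null abundance baseline)
#' from the transcribed cDNA library.
#'
#' @slot fragments GRanges of fragment intervals.
#' @slot totalUnique number of fragments after duplicate removal.
#' @slot label "input" or "cdna".
#' @slot replicate replicate identifier.
#' @slot cellLine cell line identifier.
#' @export
setClass("FragmentLibrary",
  representation(fragments = "GRanges", totalUnique = "integer",
                 label = "character", replicate = "character",
                 cellLine = "character")
)

setValidity("FragmentLibrary", function(object) {
  msg <- character()
  if (!object@label %in% c("input", "cdna"))
    msg <- c(msg, "label must be 'input' or 'cdna'")
  if (object@totalUnique != length(object@fragments))
    msg <- c(msg, "totalUnique must equal the number of fragments")
  if (length(msg)) msg else TRUE
})

#' @rdname FragmentLibrary-class
#' @param fragments GRanges of fragment intervals.
#' @param label library type, "input" or "cdna".
#' @param replicate,cellLine provenance identifiers.
#' @return A `FragmentLibrary`.
#' @export
fragmentLibrary <- function(fragments, label,
                            replicate = "rep1", cellLine = "cellA") {
  new("FragmentLibrary", fragments = fragments,
      totalUnique = length(fragments), label = label,
      replicate = replicate, cellLine = cellLine)
}

#' @rdname FragmentLibrary-class
#' @param x a `FragmentLibrary`.
#' @export
fragments <- function(x) x@fragments

#' @rdname FragmentLibrary-class
#' @export
totalUnique <- function(x) x@totalUnique

#' @rdname FragmentLibrary-class
#' @export
libraryLabel <- function(x) x@label

setMethod("show", "FragmentLibrary", function(object) {
  cat("FragmentLibrary <", object@label, "> ", object@cellLine, "/",
      object@replicate, ": ", object@totalUnique,
      " unique fragments\n", sep = "")
})

#' Binned genome-wide signal track
#'
#' bedGraph-backed coverage values on a fixed-width genome-aligned binning,
#' used for ChIP/INPUT fold-enrichment computation. Values are dense per
#' chromosome (one value per bin, zero where the bedGraph was silent).
#'
#' @slot values named list, one numeric vector per chromosome.
#' @slot binWidth bin width in bp.
#' @slot seqinfo Seqinfo of the underlying assembly.
#' @slot label mark name ("H3K27ac", ..., or "INPUT").
#' @export
setClass("SignalTrack",
  representation(values = "list", binWidth = "integer",
                 seqinfo = "Seqinfo", label = "character")
)

setValidity("SignalTrack", function(object) {
  msg <- character()
  sl <- seqlengths(object@seqinfo)
  if (!identical(names(object@values), names(sl)))
    msg <- c(msg, "values must be named by the assembly chromosomes, in order")
  nb <- ceiling(sl / object@binWidth)
  if (!all(lengths(object@values) == nb))
    msg <- c(msg, "per-chromosome value count must match ceiling(length/binWidth)")
  if (any(unlist(object@values, use.names = FALSE) < 0))
    msg <- c(msg, "signal values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SignalTrack-class
#' @param values named list of per-chromosome bin values.
#' @param binWidth bin width in bp.
#' @param seqinfo assembly `Seqinfo`.
#' @param label track label.
#' @return A `SignalTrack`.
#' @export
signalTrack <- function(values, binWidth, seqinfo, label = "signal") {
  new("SignalTrack", values = values, binWidth = as.integer(binWidth),
      seqinfo = seqinfo, label = label)
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack <", object@label, ">: ",
      sum(lengths(object@values)), " bins of ", object@binWidth,
      " bp over ", length(object@values), " chromosomes\n", sep = "")
})

#' Hi-C contact matrices at fixed resolution
#'
#' One symmetric non-negative contact-count matrix per chromosome, with
#' bin i covering `[(i-1)*resolution, i*resolution)` in 0-based genomic
#' coordinates.
#'
#' @slot matrices named list of per-chromosome square matrices.
#' @slot resolution bin size in bp (40 kb in the study this emulates).
#' @slot seqinfo assembly `Seqinfo`.
#' @export
setClass("ContactMatrix",
  representation(matrices = "list", resolution = "integer",
                 seqinfo = "Seqinfo")
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
  for (nm in names(object@matrices)) {
    m <- object@matrices[[nm]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      msg <- c(msg, paste0(nm, ": contact matrix must be square"))
    else {
      if (any(m < 0)) msg <- c(msg, paste0(nm, ": contacts must be >= 0"))
      if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, paste0(nm, ": contact matrix must be symmetric"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ContactMatrix-class
#' @param matrices named list of symmetric matrices, one per chromosome.
#' @param resolution bin size in bp.
#' @param seqinfo assembly `Seqinfo`.
#' @return A `ContactMatrix`.
#' @export
contactMatrix <- function(matrices, resolution, seqinfo) {
  new("ContactMatrix", matrices = matrices,
      resolution = as.integer(resolution), seqinfo = seqinfo)
}

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix: ", length(object@matrices), " chromosomes at ",
      object@resolution, " bp resolution (",
      paste(vapply(object@matrices, nrow, 1L), collapse = "/"),
      " bins)\n", sep = "")
})

#' Genomic feature catalog for single-category enhancer classification
#'
#' Per-category interval sets plus the priority order used to resolve an
#' enhancer overlapping several features into a single category. The
#' default priority places repetitive sequence first, then TSS-proximal,
#' 5'UTR, 3'UTR, first intron, other intron, exon; anything else is
#' intergenic. TE subclasses (LINE/SINE/LTR/DNA) are carried in the name
#' column of the repetitive set.
#'
#' @slot categories named list of GRanges, one per category (no
#'   "intergenic" entry; it is the fallback).
#' @slot priority character vector ordering the categories.
#' @export
setClass("FeatureCatalog",
  representation(categories = "list", priority = "character")
)

setValidity("FeatureCatalog", function(object) {
  msg <- character()
  if (!all(object@priority %in% names(object@categories)))
    msg <- c(msg, "every priority entry must name a category")
  if (!all(vapply(object@categories, is, TRUE, "GRanges")))
    msg <- c(msg, "categories must be GRanges")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureCatalog-class
#' @param categories named list of GRanges.
#' @param priority category order; defaults to all categories in the order
#'   given.
#' @return A `FeatureCatalog`.
#' @export
featureCatalog <- function(categories,
                           priority = names(categories)) {
  new("FeatureCatalog", categories = categories, priority = priority)
}

setMethod("show", "FeatureCatalog", function(object) {
  cat("FeatureCatalog:", paste(object@priority, collapse = " > "),
      "> intergenic\n")
})
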
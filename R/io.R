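# Readers and writers for the plain-text interchange formats of the
# pipeline. All coordinate conversion to/from the internal 1-based GRanges
# representation happens here: BED/bedGraph/TAD/contact files are 0-based
# half-open, GTF and the QTL table are 1-based inclusive. Readers validate
# per line and report the offending file and line number.

.splitLines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track")]
}

.lineError <- function(path, i, what) {
  stop(sprintf("%s: line %d: %s", path, i, what), call. = FALSE)
}

#' Read/write BED interval files
#'
#' BED3 or BED6, tab-separated, 0-based half-open. Malformed lines raise an
#' error naming the line; intervals with `start >= end` are rejected. The
#' returned set is sorted by (chromosome, start, end); input order is not
#' preserved.
#'
#' @param path file path.
#' @param expectScore if TRUE, require >= 5 columns and keep the score.
#' @return `readBed`: a `GRanges` with optional `name`/`score` metadata.
#' @export
readBed <- function(path, expectScore = FALSE) {
  lines <- .splitLines(path)
  n <- length(lines)
  if (n == 0)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (expectScore) 5L else 3L
  bad <- which(nf < minf)
  if (length(bad))
    .lineError(path, bad[1], sprintf("expected >= %d tab-separated fields, got %d",
                                     minf, nf[bad[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) .lineError(path, bad[1], "non-numeric coordinate")
  bad <- which(start0 < 0)
  if (length(bad)) .lineError(path, bad[1], "negative start")
  bad <- which(start0 >= end0)
  if (length(bad)) .lineError(path, bad[1],
                              sprintf("empty or inverted interval [%s, %s)",
                                      start0[bad[1]], end0[bad[1]]))
  strand <- rep("*", n)
  if (any(nf >= 6L)) {
    s <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else ".", "")
    bad <- which(!s %in% c("+", "-", ".", "*"))
    if (length(bad)) .lineError(path, bad[1], sprintf("bad strand '%s'", s[bad[1]]))
    strand <- ifelse(s == ".", "*", s)
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (any(nf >= 4L))
    mcols(gr)$name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else ".", "")
  if (any(nf >= 5L)) {
    sc <- vapply(fields, function(f) if (length(f) >= 5L) f[5L] else "0", "")
    mcols(gr)$score <- suppressWarnings(as.numeric(sc))
  }
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname readBed
#' @param gr intervals to write.
#' @return `writeBed`: invisibly, the path.
#' @export
writeBed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else NULL
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else NULL
  st <- as.character(strand(gr))
  cols <- list(as.character(seqnames(gr)),
               format(bedStart(gr), scientific = FALSE, trim = TRUE),
               format(bedEnd(gr), scientific = FALSE, trim = TRUE))
  if (!is.null(nm) || !is.null(sc) || any(st != "*")) {
    cols[[4]] <- if (is.null(nm)) rep(".", length(gr)) else nm
    cols[[5]] <- if (is.null(sc)) rep("0", length(gr)) else
      format(sc, scientific = FALSE, trim = TRUE)
    cols[[6]] <- ifelse(st == "*", ".", st)
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read/write chromosome sizes (two-column text)
#'
#' @param path file path.
#' @return `readChromSizes`: a `Seqinfo`.
#' @export
readChromSizes <- function(path) {
  lines <- .splitLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) .lineError(path, bad[1], "expected 'chrom<TAB>length'")
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad)) .lineError(path, bad[1], "chromosome length must be a positive number")
  genomeAssembly(vapply(fields, `[`, "", 1L), len)
}

#' @rdname readChromSizes
#' @param assembly a `Seqinfo`.
#' @export
writeChromSizes <- function(assembly, path) {
  writeLines(paste(seqlevels(assembly),
                   format(seqlengths(assembly), scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read/write a binned signal track as bedGraph
#'
#' The bedGraph is 0-based half-open. `readBedGraph` resamples onto the
#' requested genome-aligned fixed-width binning (values are averaged,
#' weighted by covered bp; uncovered bins are 0), yielding a
#' [SignalTrack-class].
#'
#' @param path file path.
#' @param assembly a `Seqinfo`.
#' @param binWidth target bin width in bp.
#' @param label track label.
#' @return `readBedGraph`: a `SignalTrack`.
#' @export
readBedGraph <- function(path, assembly, binWidth = 100L, label = "signal") {
  lines <- .splitLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) .lineError(path, bad[1], "expected 4 bedGraph fields")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  bad <- which(is.na(s0) | is.na(e0) | is.na(v) | s0 < 0 | s0 >= e0)
  if (length(bad)) .lineError(path, bad[1], "malformed bedGraph interval")
  sl <- seqlengths(assembly)
  vals <- lapply(seqlevels(assembly), function(ch) {
    nb <- ceiling(sl[[ch]] / binWidth)
    acc <- numeric(nb)
    cov <- numeric(nb)
    idx <- which(chrom == ch)
    for (i in idx) {
      # distribute the record over all bins it touches, bp-weighted
      b0 <- s0[i] %/% binWidth
      b1 <- (e0[i] - 1) %/% binWidth
      for (b in b0:b1) {
        lo <- max(s0[i], b * binWidth)
        hi <- min(e0[i], (b + 1) * binWidth, sl[[ch]])
        if (hi > lo) {
          acc[b + 1] <- acc[b + 1] + v[i] * (hi - lo)
          cov[b + 1] <- cov[b + 1] + (hi - lo)
        }
      }
    }
    ifelse(cov > 0, acc / pmax(cov, 1), 0)
  })
  names(vals) <- seqlevels(assembly)
  signalTrack(vals, binWidth, assembly, label)
}

#' @rdname readBedGraph
#' @param track a `SignalTrack`.
#' @export
writeBedGraph <- function(track, path) {
  out <- unlist(lapply(names(track@values), function(ch) {
    v <- track@values[[ch]]
    n <- length(v)
    s0 <- (seq_len(n) - 1L) * track@binWidth
    e0 <- pmin(s0 + track@binWidth, seqlengths(track@seqinfo)[[ch]])
    paste(ch, s0, e0, format(v, scientific = FALSE, trim = TRUE), sep = "\t")
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read/write gene models as GTF
#'
#' Consumes `gene`, `exon`, `five_prime_utr` and `three_prime_utr` features
#' (1-based inclusive, converted here). Returns the gene table used by the
#' annotation module: one row per gene with span, strand, and TSS (the
#' 5' end of the gene span).
#'
#' @param path file path.
#' @return `readGtfGenes`: list with `genes` (GRanges with `gene_id` and
#'   `tss` 0-based metadata), `exons`, `utr5`, `utr3` (GRanges with
#'   `gene_id`).
#' @export
readGtfGenes <- function(path) {
  lines <- .splitLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) .lineError(path, bad[1], "expected 9 GTF fields")
  feat <- vapply(fields, `[`, "", 3L)
  keep <- feat %in% c("gene", "exon", "five_prime_utr", "three_prime_utr")
  fields <- fields[keep]; feat <- feat[keep]
  chrom <- vapply(fields, `[`, "", 1L)
  s1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  e1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  st <- vapply(fields, `[`, "", 7L)
  attr9 <- vapply(fields, `[`, "", 9L)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attr9)
  if (any(is.na(s1) | is.na(e1) | s1 > e1))
    stop(path, ": malformed GTF coordinates")
  gr <- GRanges(chrom, IRanges(s1, e1), strand = ifelse(st %in% c("+", "-"), st, "*"))
  mcols(gr)$gene_id <- gid
  genes <- gr[feat == "gene"]
  mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "-",
                             bedEnd(genes) - 1L, bedStart(genes))
  list(genes = genes,
       exons = gr[feat == "exon"],
       utr5 = gr[feat == "five_prime_utr"],
       utr3 = gr[feat == "three_prime_utr"])
}

#' @rdname readGtfGenes
#' @param geneModel a list as returned by `readGtfGenes` (or built by the
#'   simulator) with elements `genes`, `exons`, `utr5`, `utr3`.
#' @export
writeGtfGenes <- function(geneModel, path) {
  fmtFeat <- function(gr, feat) {
    if (length(gr) == 0) return(character())
    paste(as.character(seqnames(gr)), "starrcall", feat,
          start(gr), end(gr), ".",
          ifelse(as.character(strand(gr)) == "*", ".", as.character(strand(gr))),
          ".", sprintf('gene_id "%s";', mcols(gr)$gene_id), sep = "\t")
  }
  out <- c(fmtFeat(geneModel$genes, "gene"),
           fmtFeat(geneModel$exons, "exon"),
           fmtFeat(geneModel$utr5, "five_prime_utr"),
           fmtFeat(geneModel$utr3, "three_prime_utr"))
  writeLines(out, path)
  invisible(path)
}

#' Read/write a QTL table
#'
#' Tab-separated columns `chrom start end trait source` with 1-based
#' inclusive coordinates (animal-QTLdb-style export), converted to the
#' internal convention here. A header line starting with "chrom" is
#' skipped.
#'
#' @param path file path.
#' @return `readQtls`: `GRanges` with `trait` and `source` metadata.
#' @export
readQtls <- function(path) {
  lines <- .splitLines(path)
  if (length(lines) && startsWith(lines[1], "chrom")) lines <- lines[-1]
  if (length(lines) == 0) return(GRanges(trait = character(), source = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) .lineError(path, bad[1], "expected chrom/start/end/trait[/source]")
  s1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s1) | is.na(e1) | s1 < 1 | s1 > e1)
  if (length(bad)) .lineError(path, bad[1], "malformed 1-based QTL interval")
  gr <- GRanges(vapply(fields, `[`, "", 1L), IRanges(s1, e1))
  mcols(gr)$trait <- vapply(fields, `[`, "", 4L)
  mcols(gr)$source <- vapply(fields, function(f)
    if (length(f) >= 5L) f[5L] else ".", "")
  gr
}

#' @rdname readQtls
#' @param qtls `GRanges` with `trait`/`source` metadata.
#' @export
writeQtls <- function(qtls, path) {
  lines <- paste(as.character(seqnames(qtls)), start(qtls), end(qtls),
                 mcols(qtls)$trait,
                 if (is.null(mcols(qtls)$source)) "." else mcols(qtls)$source,
                 sep = "\t")
  writeLines(c("chrom\tstart\tend\ttrait\tsource", lines), path)
  invisible(path)
}

#' Read/write Hi-C contact matrices as dense text
#'
#' One file per chromosome: a header line `#chrom<TAB>resolution<TAB>nbins`
#' followed by the dense tab-separated matrix.
#'
#' @param paths named character vector of file paths (names = chromosomes);
#'   for `writeContactMatrix`, a directory.
#' @param assembly a `Seqinfo`.
#' @return `readContactMatrix`: a [ContactMatrix-class].
#' @export
readContactMatrix <- function(paths, assembly) {
  mats <- list()
  res <- NULL
  for (ch in names(paths)) {
    lines <- readLines(paths[[ch]])
    hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    if (length(hdr) < 3L) stop(paths[[ch]], ": line 1: bad contact-matrix header")
    res0 <- as.integer(hdr[2]); nb <- as.integer(hdr[3])
    if (!is.null(res) && res0 != res)
      stop("contact matrices disagree on resolution")
    res <- res0
    m <- do.call(rbind, lapply(lines[-1], function(l)
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
    if (nrow(m) != nb || ncol(m) != nb)
      stop(paths[[ch]], ": matrix dimensions disagree with header")
    mats[[hdr[1]]] <- m
  }
  contactMatrix(mats, res, assembly)
}

#' @rdname readContactMatrix
#' @param m a `ContactMatrix`.
#' @param dir output directory; files are named `contacts_<chrom>.tsv`.
#' @return `writeContactMatrix`: named vector of written paths.
#' @export
writeContactMatrix <- function(m, dir) {
  out <- character()
  for (ch in names(m@matrices)) {
    p <- file.path(dir, paste0("contacts_", ch, ".tsv"))
    mat <- m@matrices[[ch]]
    writeLines(c(paste0("#", ch, "\t", m@resolution, "\t", nrow(mat)),
                 apply(mat, 1, paste, collapse = "\t")), p)
    out[[ch]] <- p
  }
  out
}

#' Read/write a gene expression table
#'
#' Two tab-separated columns: gene id and FPKM. A `gene_id` header is
#' skipped.
#'
#' @param path file path.
#' @return `readExpression`: named numeric vector of FPKM by gene id.
#' @export
readExpression <- function(path) {
  lines <- .splitLines(path)
  if (length(lines) && startsWith(lines[1], "gene_id")) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) .lineError(path, bad[1], "expected 'gene_id<TAB>fpkm'")
  fpkm <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(fpkm) | fpkm < 0)
  if (length(bad)) .lineError(path, bad[1], "FPKM must be a non-negative number")
  stats::setNames(fpkm, vapply(fields, `[`, "", 1L))
}

#' @rdname readExpression
#' @param fpkm named numeric vector.
#' @export
writeExpression <- function(fpkm, path) {
  writeLines(c("gene_id\tfpkm",
               paste(names(fpkm), format(fpkm, scientific = FALSE, trim = TRUE),
                     sep = "\t")), path)
  invisible(path)
}
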
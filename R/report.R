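# Summary statistics, the report layer, the declarative run configuration
# and the full-pipeline orchestrator.

#' Percentage with round-half-up at two decimals
#'
#' Computed in exact integer arithmetic so that printed fractions like
#' 863/2576 reproduce as 33.50 regardless of floating-point representation.
#'
#' @param count numerator (0 <= count <= denominator).
#' @param denominator positive count.
#' @return Percent value rounded half-up to 2 decimals.
#' @examples
#' percentOf(863, 2576)  # 33.50
#' percentOf(500, 2576)  # 19.41
#' @export
percentOf <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(count < 0 | count > denominator))
    stop("count must lie in [0, denominator]")
  # percent * 100 = 10^4 * count / denominator, rounded half-up
  floor((2 * 1e4 * count + denominator) / (2 * denominator)) / 100
}

.summaryTable <- function(labels, counts, denominator) {
  if (denominator == 0)
    return(data.frame(label = labels, count = counts,
                      denominator = denominator, percent = NA_real_))
  data.frame(label = labels, count = as.integer(counts),
             denominator = as.integer(denominator),
             percent = percentOf(counts, denominator))
}

#' Build the summary report from completed stage outputs
#'
#' Aggregates per-category counts with percentages: feature classes and TE
#' subclasses, open/closed accessibility, chromatin-state classes, and
#' QTL/trait counts. Every percentage denominator is the non-redundant
#' union enhancer count. With an empty enhancer set a zero-count report is
#' returned and no division is performed.
#'
#' @param stages named list with elements `union` (GRanges),
#'   `classification` (from [classifyEnhancers()]), `accessibility`
#'   (factor), `states` (factor), `qtlSummary` (from
#'   [qtlEnhancerOverlap()]). A missing element is an error naming the
#'   stage.
#' @return List of `data.frame` summary tables (`features`, `teClasses`,
#'   `accessibility`, `states`, `qtl`).
#' @export
buildReport <- function(stages) {
  need <- c("union", "classification", "accessibility", "states",
            "qtlSummary")
  missing <- setdiff(need, names(stages))
  if (length(missing))
    stop("missing stage output: ", paste(missing, collapse = ", "))
  n <- length(stages$union)
  catLevels <- c("repetitive", "tss_proximal", "utr5", "utr3",
                 "first_intron", "other_intron", "exon", "intergenic")
  catCount <- table(factor(stages$classification$category, levels = catLevels))
  teCount <- table(factor(stages$classification$te_class, levels = .teClasses))
  accCount <- table(stages$accessibility)
  stCount <- table(stages$states)
  list(
    features = .summaryTable(names(catCount), as.integer(catCount), n),
    teClasses = .summaryTable(names(teCount), as.integer(teCount), n),
    accessibility = .summaryTable(names(accCount), as.integer(accCount), n),
    states = .summaryTable(names(stCount), as.integer(stCount), n),
    qtl = data.frame(label = c("nonredundant_qtls", "traits"),
                     count = c(stages$qtlSummary$nNonredundantQtls,
                               stages$qtlSummary$nTraits),
                     denominator = NA_integer_, percent = NA_real_))
}

#' Write a report as TSV tables and machine-readable JSON
#'
#' @param report list of tables from [buildReport()].
#' @param dir output directory.
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report))
    utils::write.table(report[[nm]], file.path(dir, paste0("report_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report, jp, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(jp)
}

.configDefaults <- function() list(
  seed = 1L, n_chroms = 2L, chrom_length = 2.5e6, n_genes = 200L,
  repeat_fraction = 0.45, n_enhancers = 20L, enhancer_length = 600L,
  activity_min = 3, activity_max = 6, n_fragments = 1e5,
  window_width = 600L, pseudo = 1, min_strength = 1.0, max_p = 0.001,
  max_fdr = 0.1, min_reciprocal = 0.5, tss_window = 2000L, alpha = 0.05,
  silent_fraction = 0.3, open_fraction = 0.2,
  cell_lines = c("cellA", "cellB"), replicates = c("rep1", "rep2"))

#' Read and validate a run configuration
#'
#' A flat YAML document holding every pipeline parameter; unknown keys are
#' rejected (typos should fail loudly, not silently fall back to a
#' default). Missing keys take the package defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Named list of resolved parameters.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop(path, ": unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a study under the configuration, calls enhancers per cell
#' line and replicate under the configured thresholds, builds the
#' replicate-consensus, cross-cell-line shared and union sets, annotates
#' the union (feature categories, nearest genes, expression bins),
#' integrates chromatin (accessibility, state classes, open-vs-closed
#' mark comparison), links enhancers to traits (QTL filter and overlap,
#' TAD co-membership, Hi-C contact significance), and writes the summary
#' report. All outputs are plain text and byte-reproducible for a fixed
#' configuration; the resolved configuration is written next to them.
#'
#' @param config resolved configuration from [readRunConfig()].
#' @param outDir output directory (created).
#' @param writeOutputs set FALSE to skip file output and return results
#'   only.
#' @return Invisibly, a list with `study`, `calls`, `sets`, `annotation`,
#'   `chromatin`, `links`, `report`.
#' @export
runPipeline <- function(config = readRunConfig(), outDir = NULL,
                        writeOutputs = !is.null(outDir)) {
  simCfg <- simConfig(
    nChroms = config$n_chroms, chromLength = config$chrom_length,
    nGenes = config$n_genes, repeatFraction = config$repeat_fraction,
    nEnhancers = config$n_enhancers, enhancerLength = config$enhancer_length,
    activityRange = c(config$activity_min, config$activity_max),
    nInputFrags = config$n_fragments, nCdnaFrags = config$n_fragments,
    silentFraction = config$silent_fraction,
    openFraction = config$open_fraction, seed = config$seed)
  study <- simulateStudy(simCfg, cellLines = config$cell_lines,
                         replicates = config$replicates)
  g <- study$genome

  calls <- list()
  for (cl in names(study$libraries))
    for (rp in names(study$libraries[[cl]])) {
      sw <- scoreWindows(study$libraries[[cl]][[rp]]$cdna,
                         study$libraries[[cl]][[rp]]$input,
                         g$assembly, config$window_width, config$pseudo)
      calls[[cl]][[rp]] <- callEnhancers(
        sw, config$min_strength, config$max_p, config$max_fdr,
        provenance = paste(cl, rp, sep = "/"))
    }
  sets <- consensusAndUnion(calls, config$min_reciprocal)
  un <- sets$union

  catalog <- buildCatalog(g$repeats, g$geneModel, g$assembly,
                          config$tss_window)
  classification <- classifyEnhancers(un, catalog)
  ng <- nearestGenes(un, g$geneModel$genes)
  ng$expression_bin <- as.character(
    expressionBin(ifelse(is.na(ng$gene_id), 0,
                         study$expression[ng$gene_id])))

  accessibility <- classifyAccessibility(un, study$peaks$ATAC)
  states <- stateClass(un, study$peaks)
  comparison <- if (length(un) && nlevels(droplevels(accessibility)) == 2)
    markComparison(un, accessibility, study$tracks) else NULL

  qtls <- filterQtls(study$qtls, g$assembly)
  qtlSummary <- qtlEnhancerOverlap(qtls, un)
  links <- linkEnhancers(un, qtls, g$geneModel$genes, study$hic$tads,
                         study$hic$contacts, config$alpha)

  report <- buildReport(list(union = un, classification = classification,
                             accessibility = accessibility, states = states,
                             qtlSummary = qtlSummary))

  if (writeOutputs) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(outDir, "resolved_config.yaml"))
    for (cl in names(calls))
      for (rp in names(calls[[cl]]))
        writeCallsBed(calls[[cl]][[rp]],
                      file.path(outDir, sprintf("calls_%s_%s.bed", cl, rp)))
    writeBed(un, file.path(outDir, "enhancers_union.bed"))
    writeBed(sets$shared, file.path(outDir, "enhancers_shared.bed"))
    ann <- cbind(data.frame(enhancer = seq_along(un)), classification, ng)
    utils::write.table(ann, file.path(outDir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(comparison))
      utils::write.table(comparison, file.path(outDir, "mark_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(links, file.path(outDir, "trait_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeReport(report, outDir)
  }
  invisible(list(study = study, calls = calls, sets = sets,
                 annotation = list(classification = classification,
                                   nearest = ng),
                 chromatin = list(accessibility = accessibility,
                                  states = states, comparison = comparison),
                 links = links, report = report))
}

#' Write enhancer calls as BED6+
#'
#' Columns: chrom, start, end, name, score = round(100 * strength),
#' strand, then p, q and provenance.
#'
#' @param calls `GRanges` from [callEnhancers()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeCallsBed <- function(calls, path) {
  if (length(calls) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  m <- mcols(calls)
  lines <- paste(as.character(seqnames(calls)), bedStart(calls),
                 bedEnd(calls), m$name, round(100 * m$strength), ".",
                 format(m$best_p, digits = 6, scientific = TRUE),
                 format(m$best_q, digits = 6, scientific = TRUE),
                 m$provenance, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
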
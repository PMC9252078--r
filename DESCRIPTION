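Package: starrcall
Title: Functional Enhancer Discovery and Regulatory Integration for STARR-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Window-based calling of functional enhancers from STARR-seq
    fragment libraries (binomial enrichment of cDNA over input plasmid in
    600 bp genomic bins with Benjamini-Hochberg FDR control), replicate
    concordance and reciprocal-overlap consensus, genomic feature and
    transposable-element annotation with background-normalized enrichment,
    integration with chromatin accessibility and histone-modification
    tracks, and linkage of enhancers to complex traits through QTL overlap,
    TAD co-membership and distance-stratified Hi-C contact significance.
    Includes a seeded synthetic-study generator (genome, annotations,
    fragment libraries with planted enhancers, chromatin tracks, expression,
    QTLs, TADs and Hi-C matrices) so the full pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
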
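---
title: "Methods: window-based STARR-seq enhancer calling and regulatory integration"
author: "starrcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based STARR-seq enhancer calling and regulatory integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical model, its
synthetic-study generator, the parameter choices that matter, and the
limits of what the desk-scale benchmarks demonstrate.

# The enhancer-calling model

STARR-seq measures enhancer activity episomally: a genomic fragment cloned
downstream of a minimal promoter transcribes itself in proportion to its
enhancer strength, so the transcribed (cDNA) library over-represents
active fragments relative to the transfected input-plasmid library.

`scoreWindows()` tiles the genome into non-overlapping windows (600 bp
default) and assigns each fragment to the window containing its midpoint,
`floor((start + end) / 2)` in BED coordinates, a midpoint on a boundary
belonging to the right-hand window. Midpoint assignment, not overlap, is
deliberate: fragments and windows are both about 600 bp, so overlap
counting would assign most fragments twice and break the conservation
property (window counts summing to the library total) that the binomial
denominator relies on.

For a window with cDNA count $c$ and input count $i$:

* strength $= (c/N_c) / (\max(i, 1)/N_i)$, the fold change of
  library-normalized representation; the pseudo-count 1 substitutes for
  $i$ only when $i = 0$, avoiding infinite strength while staying
  conservative;
* p-value $= \Pr[X \ge c]$ with
  $X \sim \mathrm{Binomial}(N_c, \max(i,1)/N_i)$, computed by the exact
  stable upper-tail complement (`pbinom(..., lower.tail = FALSE)`), never
  a normal approximation;
* q-value: Benjamini–Hochberg over informative windows only
  ($c + i > 0$). Empty windows carry no information and would only dilute
  the step-up correction; their q is `NA`.

Calls require strength > 1.0 (strictly), P < 0.001 and FDR < 0.1 — the
published criteria of the assay this package implements — and merge
adjacent or overlapping significant windows, keeping the maximum
constituent strength and minimum p/q.

**Why this null is exactly calibrated here.** The test treats the input
window fraction $i/N_i$ as the known probability that a cDNA fragment
falls in the window. That is literally true when the cDNA library is a
resample of the same molecule pool the input library represents — which
is both the biology (transcribed fragments are molecules of the
transfected pool) and the generative model of the simulator (below).
Conditional on the input counts, null cDNA counts are binomial with
exactly the stated success probability, so BH control of the FDR is
inherited rather than approximate. Had the two libraries been modeled as
independent uniform redraws, the Poisson noise of the input count would
make the test anti-conservative at any realistic depth.

**Window scheme.** Non-overlapping 600 bp tiles are the default and the
benchmarked mode. A sliding scheme can be emulated by scoring shifted
tilings and merging, but merged sliding calls systematically widen beyond
the underlying element, which degrades reciprocal-overlap matching; the
tiled mode is the one whose recovery properties are guaranteed by the
test suite.

**Replicate concordance** is Pearson correlation of per-window strengths,
by default on $\log_2(\mathrm{FC} + 0.01)$ (fold changes are
ratio-scaled; the small offset keeps zero-count windows finite), with a
linear-scale option. Windows with zero counts in both libraries of both
replicates are excluded. At desk scale the genome-wide correlation is
dominated by the ~99.8% of windows that are pure sampling noise; the
per-enhancer correlation (windows inside calls) is the informative
number, and both are reported by the acceptance script.

**Consensus and union.** Two calls are "shared" when their intersection
covers strictly more than 50% of each (strict `>`, exposed as a knob);
shared pairs collapse to their union span. The non-redundant union merges
calls at > 0 bp overlap — abutting calls stay distinct, since under
half-open coordinates they share no base.

# The synthetic study

`simulateStudy()` generates every input the pipeline consumes. All
simulators are pure functions of (config, seed): each derives its RNG
stream from the seed and its own operation name, so adding a simulator
never perturbs another, and byte-identical outputs for a fixed
configuration are a tested guarantee.

**Genome and annotations.** Default: 2 chromosomes × 2.5 Mb, 200
non-overlapping genes (3 exons, 2 introns, UTRs, strand-aware TSS and
first intron), 45% repeat content in 0.5–3 kb segments with TE subclasses
weighted LINE 50% / SINE 15% / LTR 10% / DNA 5% / other 20% — a
repeat-rich, LINE-dominated genome like the pig's. The genome size is
chosen to preserve the real study's sequencing regime at the configured
1e5 fragments per library: the real libraries carried roughly 45M unique
fragments against a 2.5 Gb genome, about 11 input fragments per 600 bp
bin, and 1e5 fragments over 5 Mb give 12 per bin. A larger toy genome at
the same library size would halve the per-bin depth and silently change
the power regime the thresholds were published for.

**Planted enhancers.** 20 elements of 600 bp, activity multipliers drawn
uniformly from [3, 6], 80% placed inside repeats, aligned to the 600 bp
analysis grid with at least two bins of separation. Grid alignment is a
simulator design choice: the window is the assay's unit of inference, so
one planted element corresponds to exactly one test, and the planted
fold-change is recovered on the same scale the caller estimates. Off-grid
elements would split across two bins and turn "sensitivity" into a
mixture of effect recovery and boundary luck.

**Fragment libraries.** The input library is the cloned pool: midpoints
uniform, lengths Normal(600, 100) clipped to [200, 1200] (the real
libraries' length distribution is only summarized as "about 600 bp"; the
normal stand-in is config-exposed), strand uniform. The cDNA library
draws fragments from that same pool with probability proportional to the
activity of the enhancer containing the fragment midpoint (1 elsewhere).
Duplicates are possible by construction — repeated transcription of one
cloned molecule. This is why the `call` front end does not deduplicate by
default: without UMIs, a repeated cDNA coordinate is indistinguishable
from a PCR duplicate, and collapsing it saturates the very enrichment
being measured. `dedupFragments()` (one fragment per
chrom/start/end/strand tuple) remains available for raw libraries.

**Chromatin tracks.** Per mark, baseline signal is noise around 1.0 in
100 bp bins; where the ground truth carries the mark, a peak spanning the
enhancer ± 300 bp is planted at 3.5–6× fold over a matched INPUT track.
Mark probabilities loosely mirror the repeat-repressed biology (H3K9me3
0.45, H3K27me3 0.35, actives 0.15–0.30, ATAC open fraction 0.2).

**Hi-C and QTLs.** Expected contact between bins at distance $d$ is
$C/(1+d)$ with $C = 100$, doubled within a TAD, multiplied by $\beta = 5$
for planted enhancer–promoter links, with Poisson counts, at 40 kb
resolution. TADs are consecutive-bin blocks of 8–16 bins. QTLs cover each
planted link (±10 kb) plus random background regions, two of them longer
than half a chromosome so the length filter has something to delete.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: GC and mappability bias (fragment
placement is positionally uniform; a chi-square uniformity property test
mirrors the real libraries' unbiasedness check), sequence content (no
FASTA), transfection immunoreaction artifacts, cross-replicate batch
structure, ICE-normalized Hi-C counts, and the scale and LD structure of
real QTL catalogs.

# Downstream analyses and their knobs

* **Feature classification**: one category per enhancer, the
  highest-priority category overlapped by ≥ 1 bp; default priority
  repetitive > TSS-proximal > 5'UTR > 3'UTR > first intron > other
  intron > exon > intergenic (config list). The repeat-first default
  reflects mutually exclusive reported categories dominated by repeats.
  TE subclass: larger overlap wins, ties to the earlier of
  LINE/SINE/LTR/DNA. The TSS-proximal window is TSS ± 2 kb — "proximity"
  is never defined by the assay's literature, so it is a named parameter.
* **Enrichment**: FC = (fraction of enhancers in feature) / (feature bp /
  genome bp). With ≥ 1 bp-overlap classification of 600 bp elements the
  numerator carries an edge inflation of order
  (element width × feature segment count / genome), so the calibration
  property (FC → 1 under uniform placement) is checked with midpoint
  classification (`method = "midpoint"`) against a disjoint catalog,
  where classification probability equals the genomic fraction exactly.
* **Expression bins**: silent = 0, low (0, 1], medium (1, 10], high
  (10, ∞) FPKM; boundaries land in the lower bin.
* **Accessibility and state**: open = ≥ 1 bp ATAC-peak overlap. State
  classes use binary peak overlap with actives {H3K4me1, H3K4me3,
  H3K27ac} and repressives {H3K9me3, H3K27me3}; a signal-threshold
  alternative (fold ≥ threshold over the call span) is provided because
  the reported subsets could have been defined either way.
* **Profiles**: 100 bins × 100 bp centered on the enhancer midpoint
  (fixed-width midpoint anchoring keeps variable-length calls
  comparable); windows crossing a chromosome edge are dropped and
  counted.
* **Rank-sum test**: two-sided by default. For n₁+n₂ ≤ 12 the null
  distribution of U comes from full enumeration of all group labelings of
  the observed values — exact under ties, which the classical exact
  distribution is not; beyond that, the normal approximation with tie and
  continuity correction.
* **Trait linkage**: QTLs longer than half their chromosome are deleted
  (exactly half is kept — the rule is "longer than"); a QTL counts when
  it overlaps an enhancer by ≥ 1 bp; non-redundancy is exact-coordinate
  deduplication (a merge-overlapping alternative sits behind a flag,
  since "non-redundant" is not defined by the source analysis). Contact
  significance is a distance-stratified Poisson upper tail: observed =
  the entry at the two anchor bins (gene anchor = TSS bin; the promoter
  is the object of the regulatory claim), expected = mean of all entries
  at that bin distance on the chromosome. "Significant Hi-C contact" has
  no published definition here; this is the simplest defensible expected
  model and is isolated behind `contactSignificance()` for replacement.
  Known limitation: intra-TAD elevation is part of the distance-average
  expected, so same-TAD pairs sit above their expected value by
  construction and the nominal α is only honored on decay-only
  (TAD-flat) matrices; the candidate flag therefore requires the
  conjunction of TAD co-membership *and* contact significance, and the
  null-calibration test uses TAD-flat matrices.

# Numerical and reporting choices

* Coordinates are BED-convention half-open at every file boundary,
  `GRanges` internally; the conversion lives in the readers/writers
  alone. Readers validate per line and fail naming file and line.
* Strict inequalities follow the published wording everywhere they
  appear: strength > 1.0, reciprocal overlap > 50%, QTL deletion for
  length > half a chromosome.
* Percentages are round-half-up at two decimals, computed in integer
  arithmetic (`floor((2·10⁴·count + den) / (2·den))`), so printed
  fractions reproduce independent of floating-point representation.
* Degenerate inputs are defined, not accidental: `cdna = 0` gives
  strength 0 and p = 1; an empty interval in a BED line is an error; a
  binning wider than the chromosome yields one whole-chromosome tile;
  `P(X ≥ 0) = 1` for empty Poisson/binomial tails.
* Benchmark sizes are chosen to keep the full suite and the acceptance
  script in the minutes range while preserving the per-bin depth
  argument above: recovery averages seeds 1–10, null calibration 20
  seeds, link recovery 5 seeds, enrichment calibration 10⁴ placements.
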
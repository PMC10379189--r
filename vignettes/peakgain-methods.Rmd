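---
title: "Methods: differential peak analysis integrated with expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential peak analysis integrated with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgain)
```

## The analysis model

`peakgain` implements the comparison of a histone-mark ChIP-seq landscape
between two conditions (a treatment such as a deacetylase overexpression,
and a control) and its integration with gene expression. The unit of
evidence is the **condition-specific peak**: a called peak in one condition
that shares no base (< 1 bp overlap) with any peak of the other condition.
Treatment-specific peaks are read as *gained* signal, control-specific
peaks as *lost* signal. This presence/absence definition is deliberately
qualitative — it is the only criterion the downstream Venn-style
intersections support without a per-peak quantitative model — and the
partition is per-peak: each input peak lands in exactly one of
common/specific for its own condition, so the two conditions' common counts
need not be equal and no merged peak universe is ever built. An optional
coverage-ratio criterion on `region_mean_signal()` can be layered on by the
user; it is off by default because it requires a normalisation model
between libraries that the inputs do not carry.

Genes are reduced to two disjoint region classes:

* the **TSS window**, the inclusive ±2 kb window around the strand-aware
  TSS (4001 bp), and
* the **gene body**, the gene interval minus the first 2 kb downstream of
  (and including) the TSS, so the two classes cannot share a base. The
  exclusion span mirrors the inclusive promoter window; `tss_exclusion = 0`
  restores the full gene span for users who prefer overlapping classes.

A gene acquires a (region, direction) call whenever at least one specific
peak of the corresponding condition overlaps that region by ≥ 1 bp. Calls
are reported, never collapsed: a gene may be gained at the TSS and lost in
the body, or even gained and lost in the same region if distinct specific
peaks say so.

Differential expression is a fold-change rule on supplied means:
up when (m_t + c)/(m_c + c) ≥ f, down when ≤ 1/f, boundaries inclusive,
with f = 1.25 and pseudocount c = 0 by default. With c = 0 and a zero
control mean, a positive treatment mean is called up and a double-zero
record is dropped. No FDR filter is applied by default because the
fold-change rule is the integration's stated contract; a q-value column
filter is available.

The integration intersects three objects: the genes within 20 kb
(edge-to-edge gap, overlap counting as 0) of any condition-specific peak of
either condition; the DEG set; and the region-change calls. From these it
derives the common genes, the lost-and-down set, and the eight
(region × direction × sign) quadrants. The lost-and-down definition accepts
a lost call in *either* region; region calls are independent, so one gene
may appear in both the TSS and body quadrant lists.

Enrichment is the exact one-sided hypergeometric upper tail
\(P[X \ge k]\), \(X \sim \mathrm{Hypergeom}(N, K, n)\), over terms with at
least one query hit, BH-corrected across the tested terms, significant at
q < 0.05. Term sets are intersected with the declared background before
testing. The background defaults to all annotated genes. No
transcript-length bias correction is attempted: the package consumes gene
sets, not read-level data, so the covariate that motivates such corrections
is absent from its inputs.

ChIP-qPCR enrichment is the closed form
\(\%\,\mathrm{input} = 100 \times 2^{(CT_\mathrm{input} - CT_\mathrm{IP})}\),
with an optional `input_dilution_log2` term (0 by default; `log2(100)` for
a 1% input) and division by a control condition for fold enrichment.

## Coordinate conventions

All public I/O follows the field's file conventions: GTF/GFF3 are 1-based
closed, BED/narrowPeak/bedGraph 0-based half-open. Internally every
interval lives in a `GRanges`, i.e. 1-based closed — the Bioconductor
convention — and conversion happens exactly once, at the readers and
writers. Overlap by ≥ k bp is `min(end) - max(start) + 1 >= k` in this
convention; adjacency is never overlap. The narrowPeak summit (column 10,
offset from peak start, −1 for absent) is used as the annotation test point
when present, falling back to the full interval, because the summit is the
best point estimate of binding while the fallback keeps plain BED6 usable.
Nearest-gene distance is measured summit-or-midpoint → TSS and reported
signed (negative upstream in the gene's orientation); the 20 kb association
is measured edge-to-edge — two deliberately different notions, one for
"where is this peak relative to a gene's start", one for "is this gene in
the peak's neighbourhood". Ties on nearest gene break to the
lexicographically smaller gene id for determinism.

## Signal profiles

Coverage is consumed as bedGraph and binned (50 bp by default — standard
metagene resolution; the bin is a parameter) by length-weighted averaging;
overlapping bedGraph records are rejected as ambiguous. Anchored profiles
extract `2*flank/bin` bins over the genomic window `[anchor − flank,
anchor + flank)` for both strands and reverse the row for minus-strand
genes, so rows read 5′→3′. Windows running past a chromosome edge are
zero-padded and flagged rather than dropped. Gene-body-rescaled metagenes
are intentionally not implemented; TSS- and TES-anchored matrices together
give the same qualitative picture without interpolation artefacts. Tracks
are compared as provided — no library-size normalisation or input
subtraction is applied, since the package receives tracks, not reads.

## The synthetic experiment generator

`synthetic_design()` fixes a miniature but complete experiment:
2 chromosomes × 2 Mb, 50 genes of 8–16 kb on both strands separated by
≥ 45 kb, 5 lost-at-TSS / 3 gained-at-TSS / 4 lost-in-body planted genes, 10
down- and 6 up-regulated genes at folds 0.5/2.0 against a common baseline
of 100, full concordance between change direction and expression sign
(`overlap_with_changes = 1`), 20 shared background peaks per condition, and
no expression noise. These defaults are the package's reference study
condition; the gap was chosen so that every planted peak is more than the
20 kb association bound (plus the TSS window and peak width) from every
other gene, making the truth table exact by construction, and the 45 kb
value is the smallest round figure satisfying that constraint. No
gained-in-body genes are planted by default (the reference condition
doesn't exercise that quadrant); the parameter exists and is tested at
non-default values.

`overlap_with_changes` is defined as the fraction of region-change genes
whose DEG sign matches their direction (lost → down, gained → up); the
remaining change genes stay expression-neutral. Unplanted genes draw their
expression ratio uniformly from [1/1.1, 1.1], a margin safely inside the
1.25 threshold, so no unplanted gene can cross it even though the band is
random. Expression noise, when enabled, is multiplicative log-normal —
non-negative, right-skewed, the standard first-order model for expression
measurements. Background peaks are placed at intergenic gap centres and
shifted by a quarter peak-width between the two conditions, so they overlap
mutually (hence are common) without being byte-identical. Coverage tracks
are flat plateaus (baseline 1, +9 under peaks): sufficient for testing
binning, profiles and region means exactly, while real peak shapes, replicate
variability and library-size effects are intentionally out of scope — a
green closure test shows the pipeline's logic is exact, not that it is
robust to read-level noise.

All placement uses integer arithmetic under one seed, so two runs of the
same design emit byte-identical data files. `perturb_dataset()` applies one
controlled mutation (drop a peak, shift a peak, flip a gene's means),
rewrites the affected files (coverage included), and recomputes the truth
table from the mutated files with plain quadratic interval arithmetic that
shares no code with the pipeline — so even a mutation with side effects
(say, a shifted peak landing near a different gene) keeps the truth exact.

## Numerical choices and degenerate inputs

* Hypergeometric tails use `stats::phyper` (exact); BH uses
  `stats::p.adjust`. The test suite cross-checks both against independent
  `choose()`-based enumeration and a hand-stepped BH, to 1e-12 relative.
* Enrichment rows are sorted by (q, p, term id); the term-id key makes
  ordering total and deterministic.
* Empty peak sets partition to empty; an empty query set, an empty
  annotation, or a query outside the background are errors, not silent
  empties.
* A gene shorter than the TSS exclusion simply has no body region and can
  receive no body call.
* Promoter windows are clipped to chromosome bounds when sizes are known;
  a window entirely off-chromosome is an error.

## Problem sizes

The test suite exercises the partition against a quadratic all-pairs oracle
on 100 random instances of up to 200 peaks each, sweeps every
hypergeometric configuration with N ≤ 25, and runs the full pipeline
closure on the 50-gene reference design plus smaller 16–20-gene variants
for the perturbation paths. These sizes were chosen to make the oracles
exhaustive where possible and the whole suite quick to run on a laptop;
none of the algorithms has super-quadratic cost in the inputs, and the
pipeline itself is routinely used on genome-scale peak sets through the
same code paths.

## Known limitations

* Peak calling, alignment and replicate handling are upstream of this
  package; it consumes their outputs as given.
* The gained/lost definition ignores peak heights; a strong-vs-weak common
  peak is "common", not "changed".
* Gene-level annotation only: UTR classes are absent from the feature
  precedence, and when no exon records are supplied each gene is treated as
  a single exon (so Intron never fires).
* Expression table semantics (normalised counts vs FPKM) are the caller's
  responsibility; the fold rule is applied to whatever means are supplied.
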
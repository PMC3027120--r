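---
title: "Methods: expression scoring, signal maps and SIC change-point screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression scoring, signal maps and SIC change-point screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsignal)
```

## The problem

RNA-seq reads fall into two alignment classes. Reads lying inside an
exon align to the genome directly; reads straddling an exon-exon
junction — on the order of a tenth of a lane for typical read lengths —
fail genomic alignment and must be rescued by a junction mapper, which
reports them against splice junctions in BED form. A gene-expression
score that ignores the second class is biased downward, most strongly
for genes with many short exons. `seqsignal` combines both classes into
one score, converts alignments into per-base coverage ("signal maps"),
and screens annotated intervals — typically 3'-UTRs — for abrupt
coverage change points in a treatment-versus-control differential map,
a signature of miRNA-mediated transcript shortening or repression that
gene-level fold change often misses (the README's worked example shows
exactly that situation).

## Coordinates and data model

Every internal coordinate is 0-based half-open; conversion happens only
at file boundaries (SAM positions are 1-based inclusive on the way in,
wiggle positions 1-based on the way out, CLI `--region` is 1-based
inclusive). A single convention internally eliminates off-by-one drift
between modules.

Annotations parse into per-chromosome lists of gene models, each with
its exon set, the exon *union* (overlapping exons counted once), and
the union length `L`. Alignments load into per-chromosome lists of
uniquely mapped reads sorted by start position with a stable sort —
the start-sorted list is the one data structure every downstream
computation (counting, coverage, windows) binary-searches into.

## Expression scoring

For gene *i* the score is `1e9 * (C_A + C_B) / (N * L)`:

* `C_A` counts unique reads whose **start** lies in the exon union.
  Start-position attribution mirrors the start-sorted storage and makes
  counting a pair of binary searches per exon; a read starting at an
  exon's last base but running into the intron still counts (and the
  statistics report classifies it exonic for the same reason). A start
  in the exons of several overlapping genes counts toward each such
  gene — no fractional assignment.
* `C_B` sums the supporting-read counts of junctions whose left *and*
  right anchor blocks each overlap some exon of the gene by at least
  one base. Requiring both anchors prevents crediting read-through
  junctions of a neighbouring gene. Junction BED scores are read as
  supporting-read counts (the junction-mapper convention); a
  `count_mode = "one"` switch treats each record as one read instead.
* `N` is the sample's unique exon-read count plus its total junction
  count, so rescued reads enter numerator and library size
  consistently.
* `L` uses the exon union rather than the plain sum of exon lengths;
  with overlapping annotation records the sum would double-count bases
  and deflate scores. For non-overlapping exons the two definitions
  coincide.

"Uniquely mapped" follows the dominant aligner convention: `NH == 1`
when the NH tag is present, otherwise MAPQ > 0. Secondary (0x100) and
supplementary (0x800) records are excluded before the uniqueness rule
is applied; unmapped records (0x4) count only toward the record total.
Paired-end data are handled per record: each mapped mate is one read,
which matches the per-read definition of `N` above. Fragment-level
(FPKM-style) collapsing is intentionally not implemented.

## Signal maps

Coverage counts, at each base, the unique reads whose aligned segments
cover it. Aligned segments are the reference-consuming M/=/X CIGAR
blocks; N gaps (introns) and D gaps (deletions) advance along the
reference without covering it, the standard pileup convention. The
computation is an event sweep — +1 at each block start, -1 at each
block end, prefix sum — over candidates located by binary search, so a
window or chromosome costs one pass over the reads that touch it. The
suite checks the sweep against a naive per-base oracle and a
conservation identity (total signal equals total aligned bases), and a
runtime check confirms approximately linear growth from 1e4 to 1e6
reads.

Junction-rescued reads are *excluded* from signal maps: coverage is
built from the SAM/BAM evidence only. Their anchor placement in BED is
junction-relative and mixing the two evidence classes would make the
differential maps depend on the junction mapper's anchor conventions.

Group averages and differential maps (`mean(A) - mean(B)`, element
wise) are real-valued tracks; raw coverage stays integer.

## Change-point model

Within one interval the differential signal `x_1..x_n` is modelled as
independent Gaussian. Under the null both mean and variance are
constant (2 free parameters); under the single-change alternative at
split `k` each side has its own mean and variance (4 parameters). With
ML variance estimates (divide by `n`) the criteria reduce to

```
SIC_0    = n log(2 pi s2)  + n + 2 log n
SIC(k)   = n log(2 pi) + k log(s1_k) + (n-k) log(s2_k) + n + 4 log n
```

A change is accepted when `min_k SIC(k) < SIC_0`; binary segmentation
then recurses into both sides until nothing is accepted, a segment
drops below `2 * min_seg`, or `max_cp` is reached. Reported positions
are the 0-based offsets of the first element right of each split,
listed in ascending order of their single-split SIC on the *full*
interval and filtered to beat `SIC_0` there — this keeps the reported
list interpretable as candidate single splits while the recursion
still finds multiple changes. Intervals are ranked by
`delta = SIC_0 - min SIC`, descending.

Numerical guards: segment variances are floored at `eps = 1e-8`, so an
exactly constant segment contributes a large negative but finite
log-likelihood instead of an infinity; `min_seg = 10` bases keeps
variance estimates meaningful and suppresses spurious splits hard
against interval ends. Both are arguments, not constants. Useful
identities the tests exploit: SIC differences are invariant to adding a
constant to `x`; scaling `x` by `c` adds exactly `2 n log c` to every
SIC; splitting two identical halves costs exactly the extra-parameter
penalty `2 log n`.

At these settings the detector's measured operating characteristics
(recomputed by `scripts/acceptance.R` at every run) are: a 3-sigma mean
shift in the middle of a 500-base interval is localised within 10 bases
in effectively every replicate, and pure N(0,1) noise yields a change
point in well under 10% of 500-base intervals — the `p log n` penalty
is doing the false-positive control, with no separate significance
threshold to tune.

## Synthetic data: what it emulates, what it does not

The generator builds a toy genome (default: 2 chromosomes of 100 kb,
20 three-exon genes, 200-base exons, 300-base introns), then per sample
10,000 reads of 50 bases: 10% junction reads (the fraction typical of
this read length), 5% multi-mapped records (`NH:i:2`, MAPQ 0), 5%
unmapped records (flag 0x4), remainder uniquely mapped exon reads
placed uniformly over exon unions. Class allocation is exact
(`round(frac * n_reads)`), one derived pseudo-random stream per
sample, and a fixed seed reproduces every output byte. Each gene's
last exon doubles as its 3'-UTR interval; a planted drop-out thins
treatment-sample reads starting in the distal `utr_fraction` of that
exon with probability `amplitude`, so the differential map contains a
genuine change point *inside* the interval (drop-outs at an interval
edge would be undetectable by construction, as real 3'-end events
would be in windows that start at the event).

Deliberate idealisations: uniform coverage within genes (no 3' bias or
GC effects), error-free pure-match CIGARs for exon reads, no
quality-score model, uniform gene expression levels, non-overlapping
genes. Consequently the passing tests demonstrate algorithmic
correctness (counts, coverage, ranking, formats) under clean
conditions — they do not establish robustness to coverage
heterogeneity, overlapping annotation or aligner artefacts in real
libraries. The counting rules themselves (start-position attribution,
both-anchor junction matching) are conventions a user should know when
comparing against overlap-based counters, which can differ at exon
boundaries.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately small
scale — 10,000-read samples, 50 kb chromosomes, 100-400 replicate
simulations, one 1e6-read timing fixture — sizes chosen so the whole
suite completes in a few minutes while still exercising every code
path against brute-force oracles. The library itself is deterministic;
all stochastic tests fix seeds, and results are independent of
execution order across intervals (ranking a set of UTRs is
embarrassingly parallel by construction).

## Known limitations

* Gene-level only: no isoform deconvolution, by design.
* RPKM/FPKM only: no TMM/DESeq-style normalisation; cross-sample
  comparisons inherit RPKM's compositional caveats. Only fold change is
  provided for differential comparison.
* Start-position counting undercounts genes shorter than a read length
  relative to overlap counting (a read starting just upstream of a tiny
  exon is not credited).
* The Gaussian change-point model treats neighbouring bases as
  independent; read length induces local correlation in real coverage,
  so SIC deltas on real data are better used as a ranking statistic
  than as calibrated evidence (which is how the screening is framed).
* Wiggle I/O supports the `variableStep span=1` dialect only; no
  BigWig/bedGraph.
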
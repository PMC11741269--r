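---
title: "Dissecting an embryonic cis-regulatory landscape with crmscape"
author: "crmscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an embryonic cis-regulatory landscape with crmscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscape)
```

## The biological question

During vertebrate germ-layer specification, maternally deposited
transcription factors (TFs) bind cis-regulatory modules (CRMs) of the naive
embryonic genome before zygotic genome activation, mark them for coactivator
(Ep300) recruitment and H3K27ac deposition, and thereby wire the
lineage-specific regulatory program. Asking whether a pair of maternal TFs
acts this way requires a chain of genomic analyses:

1. classify stage-resolved ChIP-seq peaks of a TF into **temporal occupancy
   classes** (which of three developmental stages a binding locus is
   occupied in — seven possible patterns);
2. call regions **co-occupied** by two TFs and the coactivator (here called
   FSE regions: factor A + factor B + Ep300);
3. identify **super-enhancers** (SEs) by stitching enhancer peaks and
   rank-ordering stitched loci by H3K27ac signal, cutting the scaled curve
   at its inflection;
4. call **direct target genes** by intersecting morphant (knockdown)
   differential expression with binding sites within a genomic window of
   each gene;
5. profile **motif density** around peak summits with position weight
   matrices; and
6. quantify **expression robustness** of SE-associated genes in
   single-nucleus data (cluster z-scores and the coefficient of variation,
   COV).

crmscape implements this chain as composable functions over Bioconductor
containers (`GRanges` for peaks and signal), plus seeded synthetic-data
generators that plant ground truth for every stage, so the full pipeline is
testable end to end without any external download.

## Coordinate and container conventions

All coordinates are 0-based half-open at the file boundary (BED, bedGraph)
and 1-based closed internally (`GRanges`); GFF3 (1-based) maps directly.
A single internal convention removes off-by-one drift between stages.
Strand is ignored for peaks and signal and used only to place TSSs. Peak
overlap defaults to a minimum of 1 shared base (`min_bp = 1`), exposed as a
parameter because Venn-style intersection tools differ here.

## Temporal classes and co-occupancy

`temporal_classify()` pools the three stage peak sets and single-linkage
clusters peaks by overlap: a chain a–b, b–c places all three peaks in one
locus even when a and c do not touch, matching how interval-intersection
tools behave. Each locus gets the membership pattern of the stages that
contributed peaks; the canonical class identity is the pattern itself
(e.g. `"101"` = bound early and late but not mid). Roman numerals I–VII are
a figure-level display convention that differs between published factors,
so `temporal_class_map()` is a replaceable table, with stage-unique
patterns shown as I/III/VI, pairwise-shared as II/IV/V and the persistent
pattern as VII.

`co_occupancy()` applies the same single-linkage clustering to the two TF
peak sets plus the coactivator set and flags each maximal region for the
inputs that contributed; regions with all three flags are FSE regions,
reported as the union (not intersection) of their contributing peaks
because downstream gene linking favours inclusive footprints.

## Super-enhancer calling

`stitch()` merges enhancer peaks separated by at most `stitch_gap`
(default 12,500 bp) after optionally removing peaks within `tss_exclusion`
(default 2,500 bp) of a TSS — the conventions of the established rank-order
SE callers. `rank_loci()` scores each stitched locus by
`max(signal - background, 0)` and scales both axes to [0, 1]
(`x` = ascending rank fraction, `y` = net signal over the maximum).
`find_cutoff()` scans the curve by ascending `x` and takes as cutoff the
`y` of the first point whose discrete slope to the next point exceeds 1;
loci strictly above the cutoff are SEs. Numerical choices: the strict
inequality carries a `1e-9` tolerance so a perfect diagonal (slope exactly
1 everywhere) yields zero SEs under floating point; ties in net signal
rank the wider locus higher, then coordinates; loci exactly at the cutoff
are REs (conservative, deterministic); a single locus is an RE by
convention; the criterion is invariant to rescaling the signal. Whether
input chromatin is subtracted before ranking is left to the caller
(`background` is optional and the subtraction floors at zero).

## Direct-target calling

`simple_de()` is a deliberately small DE caller used to close the loop on
synthetic data (externally produced DE tables with columns
`gene/baseMean/log2FC/pvalue/padj` are accepted verbatim everywhere
downstream). It normalizes libraries by median-of-ratios size factors,
reports `log2FC = log2((mean_treat + 1) / (mean_ctrl + 1))` on normalized
counts (pseudocount 1 stabilizes small counts, and is the reason scale
invariance of the fold change is exact only without it), and tests each
gene with a **pooled** (equal-variance) two-sample t-test on
`log2(normalized + 1)`. The pooled test, rather than the unequal-variance
(Welch) variant, is a deliberate choice: under the count model both
conditions share a per-gene dispersion — the same assumption limma and
DESeq2 make — and at 2–4 replicates the Welch–Satterthwaite approximation
is measurably conservative (about 3.4% rejections at a nominal 5% even on
exactly normal data), while the pooled test is calibrated.

`assign_peaks_to_genes()` measures peak-edge to gene-body-edge distance
(0 when overlapping), assigns each peak to its nearest gene within
`window` (default 20,000 bp; ties break to the smaller distance then the
lexicographically smaller gene id), and a TSS-based distance can be had by
passing 1-bp TSS gene bodies. `call_direct_targets()` then declares a gene
a direct target of a factor when it changes at least `fold`-fold (default
2) at `padj <= 0.05` in that factor's morphant and carries a binding site
of that factor within the window. Down in the morphant means activated by
the factor (knocking down an activator lowers its targets). Genes passing
for both factors are joint targets; joint/A-only/B-only is a disjoint
partition. The fold threshold is applied to raw (unshrunken) fold changes
and the `padj` cutoff is a config parameter, since neither is fixed by the
upstream convention this models.

## Motif profiles

`scan_pwm()` scores both strands with log2-odds PWMs (uniform background by
default); `N` scores `-Inf`, and the default hit threshold is 80% of each
PWM's maximal score — a conventional default, since external motif tools
keep their thresholds internal. `summit_histogram()` bins hit midpoints by
offset from the peak summit over a ±1,000 bp window in 20 bp bins (100
bins); peaks without a recorded summit fall back to their midpoint with a
message. `combinatorial_content()` reduces per-peak presence of two motifs
to four disjoint proportions (both / A-only / B-only / neither). PWMs can
be built from consensus strings for fixtures or read from JASPAR-style
text; no de novo discovery is attempted.

## Single-nucleus statistics

`qc_filter()` removes cells below a detected-genes cutoff (default 1,500
for real data; the synthetic demo lowers it because its gene universe is
small) and then drops genes left undetected. Normalization scales each
cell to the median depth. Two conventions deserve a note:

* **z-scores** (`zscore_localization()`) are computed on log1p-normalized
  cluster means across clusters with the *sample* SD (n−1), the pandas
  default that this kind of analysis is ordinarily run with; z-scores per
  gene sum to zero either way.
* **COV** (`cov_per_gene()`) is sample SD over mean of *linear*
  (not log) depth-normalized expression. Computing COV after a log
  transform would destroy its defining property — invariance to rescaling
  a gene — so the log is applied only where means are compared across
  clusters, not where dispersion is the statistic itself. Genes below
  `min_mean` (default 0.01 normalized counts) are excluded as
  uninformative.

`se_gene_linking()` attaches genes to SE loci within 20 kb (SE takes
precedence over RE, matching the exclusive reading of "SE-associated
genes"), and `robustness_contrast()` compares named gene groups by mean
expression and mean COV with pairwise Mann–Whitney tests, BH-adjusted.

## The synthetic study and what it does (not) emulate

`simulate_study()` fans a single seed out to per-generator child seeds
(fixed offsets, documented in `SEED_OFFSETS`) and wires the generators
together; every generator is a pure function of (seed, parameters), so
reruns are byte-identical. The default study emulates the structure of a
three-stage, two-factor embryonic dataset at desk scale:

* genome: 4 chromosomes x 5 Mb, 300 non-overlapping genes;
* stage peaks: 160 loci over the 7 temporal patterns (weighted toward the
  early-unique and persistent classes, as early-blastula TF binding is),
  400 bp peaks jittered by at most a quarter width between stages;
* enhancer landscape: 200 regular-enhancer loci (1 kb, unit amplitude) and
  5 super-enhancer clusters of five 2 kb constituents spanning ~20 kb at
  10x amplitude — the ~20 kb span mirrors the typical SE footprint, and
  the resulting stitched landscape is 205 loci;
* morphant counts: negative binomial with variance = mean + dispersion x
  mean²; 30 planted direct targets (10 A-only, 15 B-only, 5 joint; 70%
  activated) at |log2FC| = 2. The demo runs at the zero-noise end of these
  conditions — dispersion 0.001, 4 replicates, base means lognormal(log
  2000, 0.5), planted peaks straddling the target gene's 5' end — chosen
  once so that exact recovery (precision = recall = 1) is the correct
  expectation rather than a lucky draw. The generator's own defaults
  (dispersion 0.05, 3 replicates, lognormal(log 200, 1) means) are the
  realistic-noise conditions used for calibration checks;
* single-nucleus matrix: Poisson-lognormal counts over the 13 reference
  cell states (5 ectodermal, 4 mesodermal, 4 endodermal,
  `default_cell_states()`); robustness is planted through the lognormal
  sigma (0.25 for SE-associated genes vs 0.8 background) and a 4x base
  rate, so elevated mean and depressed COV are independent dials; two
  marker genes per cluster are planted for z-score tests;
* motif windows: uniform-composition sequences with consensus sites
  written at known offsets.

What the generators deliberately do **not** emulate: read-level data
(alignment and peak calling are upstream of this package), realistic
genome sequence composition (motif scanning gets dedicated planted
windows), replicate-level irreproducibility (an IDR-style analysis is out
of scope; a both-replicates overlap filter can be had with
`overlapsAny`), mappability or GC structure in the signal tracks, doublets
or ambient RNA in the single-nucleus matrix, and batch effects. Passing
tests on synthetic data therefore demonstrate the correctness of the
computations and the recoverability of planted structure — not robustness
to every artifact of real sequencing data.

## Problem sizes used by the test suite

The bundled checks run the demo study (205 stitched loci, 160 temporal
loci, 300 genes, 30 targets), oracle-equivalence sweeps (200 random
instances each for temporal classification against brute-force subset
enumeration and for the SE cutoff against a naive slope scan), a
2,000-gene null for DE calibration, and 100 generator seeds of a
200-gene x 300-cell single-nucleus matrix for the COV ordering. These
sizes were chosen as the smallest at which the planted structure is
unambiguous and the statistical checks have narrow error bands.

## Known limitations

* Single-linkage clustering can chain distinct binding events into one
  locus in dense regions; counts are therefore sensitive to `min_bp`.
* `simple_de` does not shrink dispersions; at 2 replicates and low counts
  its power is far below DESeq2's, which is why external DE tables are
  accepted as first-class input.
* The SE cutoff is the classic geometric criterion; landscapes without a
  clear inflection (near-diagonal curves) legitimately yield zero SEs.
* Motif thresholds are per-PWM fractions of the maximal score; no
  background-model p-values are computed.
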
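---
title: "Methods: chromosome-scale transcriptome maps with txatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-scale transcriptome maps with txatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txatlas)
```

# The analysis

`txatlas` reconstructs, from a gene annotation and a multi-condition FPKM
matrix, the kind of chromosome-scale transcriptome map that deep RNA-seq
atlases of large plant genomes support: which loci are transcribed and what
they are (genes, transcribed pseudogenes, novel transcribed regions,
putative lincRNAs, cis-natural antisense transcripts), how expression level
and breadth relate to gene structure, how transcription is organised along
the chromosome (density tracks, changepoint segmentation, named regions),
and how co-expression clusters and gene islands ("insulae") are arranged.

The package operates downstream of read alignment and transcript
quantification: FPKM values are inputs, never computed. "Expressed" means
FPKM > 0 in at least one condition; a configurable floor exists
(`fpkm_floor`) but defaults to 0 because that is the convention the summary
statistics assume. All internal coordinates are 1-based inclusive
(GFF3-native); the only conversion to 0-based half-open coordinates happens
when a BED file is written, which keeps off-by-one drift structurally
impossible.

# Models and procedures

## TAR classification

A transcriptionally active region (TAR) is any locus — annotated gene,
pseudogene/fragment, or novel transcribed region (NTR) — with FPKM above
the floor in at least one of the conditions. Classes are taken from the
annotation: NTR status means zero overlap with any annotated gene span on
either strand (closed-interval intersection of at least 1 bp counts as
overlap). Putative lincRNAs are NTRs passing three conjunctive filters:
length strictly greater than 200 nt, longest ORF at most 300 AA (300
itself passes: the exclusion is of ORFs *longer than* 300 AA), and no
protein similarity. The similarity flag is an input column — homology
searching is outside the package's scope. The ORF scan covers all six
frames; an ORF is `ATG` ... in-frame stop, with length counted in codons
excluding the stop. cis-NATs are expressed genes overlapped by
opposite-strand transcription by at least `cisnat_min_overlap_bp` (default
1 bp, exposed because no canonical threshold exists; the overlap used is
the largest single antisense interval).

## Expression profiles and the structure bell

Breadth is the number of conditions with FPKM above the floor; the mean
expression level averages only the conditions where the locus is expressed.
Level classes follow the common semi-quantitative FPKM scale: low `< 5`,
medium `[5, 200)`, high `>= 200`. The two published descriptions of the
medium/high boundary disagree by the closure of the 200 endpoint; the
package uses `[5, 200)` because 200 FPKM is also where the structure curves
turn over, which makes the half-open convention self-consistent. A locus is
organ-specific when all of its expressed conditions belong to one organ.

For the expression-vs-structure analysis, expressed genes are ranked by
mean expression level (ties broken by locus id, so the binning is
deterministic) and split into 30 contiguous rank blocks whose sizes differ
by at most one. Structural features — spliced transcript length, exon
number, cumulative and mean intron length, mean exon length, isoform count
— are computed on the *primary transcript*, defined as the longest isoform
(ties to the lowest transcript id); which isoform the original analyses
used is not documented, and the longest-isoform convention is the common
default. Per-bin means and SDs are reported, and the inflexion of a feature
curve is the argmax of a 3-bin moving average, with a `monotone` flag when
the maximum is not interior. The low-expression bins (1–4) are reported
unmodified even though detection-threshold artifacts can make them
unreliable; filtering them is a presentation decision left to the user.

The quartile-based outlier statistic `(Q3 - Q1) * 3 / Q3` is reported
literally, together with a conventional flagging fence `Q3 + 3 * (Q3 -
Q1)`; both use type-7 (linear interpolation) quantiles, stated explicitly
because the statistic depends on the quartile method.

## Alternative-splicing event typing

Events are defined purely structurally between isoform pairs of one gene,
then deduplicated by (type, coordinates) across all pairs:

* **IR** — an intron of one isoform lies strictly inside a single exon of
  the other.
* **ES** — an exon of one isoform lies fully within a single intron of the
  other and both isoforms share the flanking exons' inner boundaries.
* **A5SS / A3SS** — two overlapping exons share one boundary and differ at
  the other; which label applies depends on whether the moving boundary is
  a donor or an acceptor, which is strand-dependent. The flanking exon on
  the differing side must exist in both isoforms with the same facing
  boundary — without this guard every retained intron would additionally
  be called as a splice-site shift, since a merged exon and its left
  constituent share a start and differ at the end.
* **MXE** — an exon unique to each isoform, mutually non-overlapping, both
  immediately between the same shared flanking exon pair.

Terminal-exon differences (TSS/TES shifts) are not events; only internal
boundaries participate. Isoform pairs whose splice sites differ without
matching any canonical pattern are recorded once as `complex` and excluded
from the five-type proportion denominator, keeping the proportions
comparable across datasets. A gene is *multiexonic* when any isoform has at
least two exons (not just the primary one: an intron-retaining isoform is
often the longest).

## Window tracks, regions, segmentation

Feature density tracks use sliding windows (default 10 Mb, step 1 Mb;
both rescale proportionally when a scaled-down synthetic chromosome is
analysed). A feature belongs to a window when its midpoint falls in the
half-open window interval, so each feature counts once per window and
window sums over a tiling partition conserve the total count. Z-scores use
the sample (n−1) SD; a zero-variance track gets all-zero scores. The five
named regions R1/R2a/C/R2b/R3 default to boundaries proportional to the
canonical wheat-3B partition (1/68/265/387/715/774.4 Mb), with half-open
membership and a right-closed final region.

Changepoint detection is Gaussian mean-change binary segmentation written
in the package: the best two-mean split of a segment is accepted when twice
the log-likelihood gain exceeds `2 log(n)` (a BIC-style penalty), recursing
on both sides. The noise variance is estimated once, globally, from first
differences (`sum(diff(x)^2) / (2(n-1))`), which is insensitive to the mean
shifts themselves and makes the changepoint set invariant under affine
transforms of the series. Two caveats are deliberate: exact changepoint
counts can differ from other BIC implementations (penalty bookkeeping
differs between tools), and segmentation of the default *overlapping*
window series inherits its strong autocorrelation — on such series the
first-difference variance underestimates the effective noise and produces
fine-grained segments. Recovery guarantees are therefore stated, and
tested, on tracks with `window == step`; the overlapping-window option is
retained because it mirrors how such figures are conventionally drawn.

Region comparisons use per-region summaries plus pairwise Welch t tests;
regions with fewer than 2 observations are summarised but excluded from
testing. Gradients along the chromosome use Spearman rank correlation
(mid-ranks for ties; two-sided t-approximation p-value), with the distance
to the centromere measured from the midpoint of the C region.

## Co-expression, insulae, neighbour pairs

Profiles are clustered by complete-linkage agglomeration on `1 - Pearson`
distance and the tree is cut at similarity 0.641 — the two-sided critical
Pearson correlation at alpha 0.01 for 15 paired observations, computed as
`t / sqrt(t^2 + n - 2)` with `t` the 0.995 Student-t quantile at 13 df.
Complete linkage at that cut guarantees every within-cluster pair
correlates at or above the threshold. Rows are processed in locus-id order
so results are deterministic; zero-variance profiles, for which Pearson is
undefined, are put in a reserved cluster 0 and excluded from similarity
computations. Clustering uses the expressed protein-coding genes'
gene-level profiles. The package makes no promise about a particular
cluster count on real data — the contract is the deterministic cut plus
recovery of known structure on synthetic data.

Insulae are maximal runs of two or more consecutive genes with intergenic
distances (annotated gene spans, strand ignored) at or below 30 kb;
singletons are not insulae, and overlapping genes are clamped to distance
0 with a warning. Within an insula, every genomically adjacent pair is
examined: co-expressed means same cluster; orientation of the (left,
right) pair is divergent for (−,+), convergent for (+,−), tandem
otherwise. Chain counting explains why co-expressed genes can outnumber
pairs by less than a factor of two. Duplication flags are an input column.
Cluster-by-region composition uses per-cluster chi-square homogeneity
tests (cluster vs rest across regions, df = regions − 1), flagged
unreliable when more than 20% of expected counts fall below 1. Term
enrichment is a generic two-sided Fisher exact test per term with
Benjamini–Hochberg correction.

# The synthetic chromosome generator

The generator exists so that every stage can be validated by recovery
against known truth. Its defaults emulate the canonical study conditions:
a 774.4 Mb chromosome divided into R1/R2a/C/R2b/R3; per-region gene
densities (18/7/1/5/15 per Mb) producing the centromere-to-telomere
gradient; 26.7% of gene models annotated as pseudogenes/fragments with
77.5% of full genes and 54.7% of pseudogenes expressed; NTRs at 4.8/Mb, of
which 28% carry protein similarity and 22.4% of the remainder are built as
lincRNAs; a 12.2% cis-NAT rate; AS event types injected at proportions
IR .35 / A3SS .27 / ES .21 / A5SS .16 / MXE .009; and 15 conditions (5
organs × 3 stages). `scale` shrinks everything proportionally; the test
suite uses 20–155 Mb chromosomes (roughly 140 to 1,050 genes) so the full
pipeline runs in seconds, and window/step are rescaled by the same factor.

Where the underlying distributions are not published, the generator's
choices are declared artifact choices, made once:

* **FPKM model.** Eight cluster templates with strong, distinct
  organ/stage modulation: two constitutive (all 15 conditions), five
  organ-specific (3 conditions), one single-condition. A gene's row is its
  log-normal base level (cluster-dependent median, log-sd 0.7) times its
  template times multiplicative log-normal noise (`noise_sdlog = 0.15`).
  The noise level encodes tight co-regulation within a module — what "a
  co-expression cluster" means under a 0.641 complete-linkage cut — while
  keeping between-template correlations far below the cut. Zeros come from
  the activity patterns themselves; a `dropout` knob (default 0) exists to
  stress the breadth-dependent filters but is off by default because
  random dropout inside active conditions is not a feature the cluster
  model asserts. Cluster weights depend on the region: the centromeric
  core is enriched in the broad constitutive cluster, R1 in
  leaf-preferential and R3 in spike/grain-preferential genes.
* **Structure coupling.** Expressed genes are ranked by mean expression;
  structural features are drawn with a Gaussian bell in the rank fraction,
  peaking at bin 22 of 30 (width 0.22): exon count `1 + Poisson(1 + 7 *
  bell)`, exon length log-normal with a bell term, intron lengths
  log-normal with a 150 bp floor (so every intron can host an injected
  event). A `size_breadth_coupling` coefficient (default −0.15) ties exon
  length negatively to standardised breadth, reproducing the
  compact-housekeeping-gene effect without destroying the bell.
* **Isoforms.** Extra isoforms are created only by injecting one sampled
  canonical AS event each into the primary chain. Injection bookkeeping
  keeps the introns touched by different events disjoint (and a boundary
  shift consumes both introns around its exon), which makes the classifier
  provably able to recover the injected multiset exactly — two opposite
  boundary shifts on one exon would otherwise be indistinguishable from an
  MXE, which is a fact about splicing patterns, not a classifier defect.
* **Islands.** Genes are laid out island by island: singleton with
  probability 0.6, otherwise `2 + Poisson(1)` members, intra-island gaps
  uniform in [0.5, 25] kb and inter-island gaps at least 35 kb; this puts
  about two thirds of genes in islands of mean size ~3 at the 30 kb
  threshold. Region capacity is checked and over-dense configurations
  error out.
* **Sequences.** lincRNA (and short) NTR loci are built with no start
  codon on either strand — their longest ORF is exactly 0 by construction
  — while ORF-carrying NTRs embed a 320-codon ORF and coding genes a long
  ORF scaled to transcript length.

What the generator does *not* emulate, and what passing recovery tests
therefore do not show: mapping artifacts and multi-mapping between
homoeologous copies, transcript-assembly noise, condition-dependent
library-size effects, transposable-element sequence content, and continuous
breadth variation within clusters (breadth takes the template values 15, 3
and 1 when dropout is off). Recovery results on synthetic data demonstrate
the pipeline's internal correctness, not robustness to those real-data
phenomena.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere.
* Z-scores: sample SD; zero-variance tracks give all-zero scores.
* Segmentation: `min_seg = 2`; zero-variance series yield no changepoints.
* Ties: every ranking (binning, clustering order, primary-transcript
  choice) breaks ties by lexicographic locus/transcript id.
* Empty categories, single-gene regions, missing sequences and empty
  antisense tables degrade to warnings or explicit "skipped" statuses, not
  errors; malformed files (negative FPKM, coordinates with end < start,
  orphan exons, duplicate locus ids) are hard errors naming the offending
  record.
* Percentages are reported to one decimal, the convention all summary
  tables share, so a summary's percentage field always equals its
  numerator/denominator pair at that precision.

# Problem sizes used by the tests

The checks in `tests/testthat/` run the generator at 20 Mb (~140 genes),
50 Mb (~340 genes) and 155 Mb (~1,050 genes), the last of which gives 30
expression bins of ~25 genes each — enough for the bell inflexion to be
located within the configured window — and the changepoint-recovery study
uses 50 replicated 60-window two-step tracks with noise at 20% of the step
height. These sizes were chosen so the whole suite exercises every stage,
including two full pipeline runs, in well under five minutes on a single
core.

# Known limitations

* Event typing is pairwise: a difference that is only interpretable by
  comparing three isoforms jointly is reported as `complex`.
* The 0.641 cut is tied to 15 conditions at alpha 0.01; other designs
  should recompute it with `critical_pearson()`.
* Segmentation of overlapping-window tracks over-fragments by design (see
  above); interpret those segment borders qualitatively or use
  `window == step`.
* Multicopy-pseudogene and duplication statistics are replayed from input
  counts or flags; the package does not detect paralogy.
* The chi-square comparison of expressed-vs-predicted window distributions
  (`window_count_gof()`) is provided with the 1 Mb-stepped windows, but no
  equivalence with any particular published statistic is claimed, since
  the original binning is not documented.
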
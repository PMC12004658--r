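---
title: "Windowed DMR calling and promoter methylation-expression correlation with rootMethylome"
author: "rootMethylome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed DMR calling and promoter methylation-expression correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`rootMethylome` implements the computational core of a developmental
methylome study design: whole-genome bisulfite sequencing of staged tissues
(two biological replicates per stage, e.g. the initiation stages of crown,
lateral and embryonic roots in rice) together with matched RNA-seq. The
package covers

* global weighted methylation summaries per context (CG, CHG, CHH), 100-kb
  level distributions, gene/TE metaplots, replicate QC and the coverage
  estimate;
* 50-bp windowed differential-methylation (DMR) calling with Fisher's exact
  test and a replicate-consistency filter;
* annotation of DMRs against TEs, promoters and gene bodies, and the
  DMR-associated TE length comparison against random control windows;
* the RNA-seq-side filters (transcribed-gene counts, strict DEG filter,
  variation pre-filter for co-expression analysis, classical MDS);
* per-gene promoter-bin CHH methylation versus expression correlation with
  Benjamini-Hochberg FDR control;
* a synthetic-data generator with planted, known ground truth that makes
  every stage testable without external sequencing data.

Read mapping, DE testing internals, co-expression module detection and GO
enrichment are out of scope; their outputs (cytosine reports, a DE table)
are inputs here.

# The DMR procedure

For a comparison of sample A versus sample B (each with replicates), every
chromosome is tiled into 50-bp windows. Within a window and context,
methylated read counts `mc` and total read counts `cov` are summed per
replicate; the *informative* coverage of a sample is the pooled `cov` over
its replicates, and the pooled level is `sum(mc) / sum(cov)`. A window is a
DMR when all of the following hold:

1. informative coverage is at least 20 in each sample (the rule can be
   switched to a joint `>= 20` over both samples via
   `informativeRule = "joint"`; the per-sample default is used because a
   two-sample test needs information on both sides);
2. the absolute pooled level difference exceeds the context threshold: 0.5
   (CG), 0.3 (CHG), 0.1 (CHH);
3. the two-sided Fisher exact p-value on the pooled 2x2 count table
   ([methylated, unmethylated] x [A, B]) is below 0.05;
4. every A-replicate x B-replicate pairing (four pairings with two
   replicates per sample) shows a level difference that exceeds the same
   threshold with the sign of the pooled difference. Pairings with zero
   coverage on either side fail the filter — a conservative choice, since a
   level that cannot be computed cannot confirm consistency.

Windows are reported individually (no merging of adjacent DMRs), with
direction `hypo` when A is less methylated than B under the A-versus-B
orientation (comparisons are expressed later-stage versus earlier-stage).
Internally coordinates are handled half-open; all written output is 1-based
inclusive.

The Fisher test is computed by summing all hypergeometric point
probabilities not exceeding the observed table's probability, with the
customary `1 + 1e-7` relative guard against floating-point ties — the same
convention as `stats::fisher.test`, against which (and against an
independent `lchoose`-based enumeration) the implementation is tested to
`1e-10` over an exhaustive sweep of tables. The implementation groups
windows by margins so genome scans with tens of thousands of windows run in
seconds.

Rationale for testing pooled counts: the procedure pools replicate counts
wherever a level is computed (a *weighted* methylation level), never
averages per-replicate levels; replicate disagreement is handled by filter
(4) rather than by a dispersion model. This keeps the caller simple and
transparent at the cost of treating the two replicates as one library in
the test — the known anti-conservativeness of that choice is exactly why
the consistency filter exists.

# DMR-TE length enrichment

For a window set (DMRs, or random controls), the lengths of all overlapped
TEs are collected, one entry per window-TE association (a TE hit by two
windows counts twice; `distinct = TRUE` switches to distinct-TE counting).
Controls are 2000 windows of 50 bp per chromosome with uniformly random
start positions, sampled with replacement so windows may overlap — with 12
chromosomes, 24,000 windows. The two length distributions are compared with
a rank-based Wilcoxon-Mann-Whitney test, and the fraction of associations
with TEs shorter than 500 bp ("short TEs") is reported per group. The
positional profile of short TEs over scaled gene bodies and 2-kb flanks is
a midpoint density per bp, strand-aware.

# Promoter methylation versus expression

The promoter is the 2-kb region upstream of the TSS, strand-aware (the
field convention), split into ten 200-bp bins with bin 1 adjacent to the
TSS, truncated at chromosome edges. Per stage, replicate counts are pooled
and each bin gets a weighted CHH level (missing when uncovered). Expression
replicates are averaged per stage and log2(x + 1)-transformed by default
(`logTransform = FALSE` correlates raw RPKM). For each gene, Pearson r is
computed between expression and each bin's methylation across stages
(pairwise-complete, at least 4 complete pairs, constant vectors excluded);
the bin with the highest *absolute* coefficient is the gene's "most related
methylated promoter region" — absolute, because both positive and negative
regulation are of interest; a signed mode is available. Ties break toward
the TSS-proximal bin. The selected p-values are BH-adjusted across genes
and a gene is classified positive/negative at q < 0.01.

Two properties of this procedure are worth knowing. First, selecting the
best of ten bins inflates the selected p-value relative to a single
pre-specified bin; the FDR is controlled over the selected values, as in
the original procedure, so the realized false-classification rate among
truly unlinked genes is a few percent at q < 0.01 (about 3-4% on synthetic
null genes), not 1%. Second, with only two stages the correlation is
undefined (n < 4); the analysis needs a multi-stage series.

A promoter is flagged *modified* when its pooled CHH level over the full
2 kb strictly exceeds 0.5; promoters with no coverage are not evaluable.

# Expression-side filters

* Transcribed genes: RPKM strictly above 1, replicates averaged per stage
  first (a both-replicates mode is available).
* DEG filter: fold change strictly above 4 (or below 1/4) and q strictly
  below 0.01; the DE table is an input, fold changes later-over-earlier.
* Variation pre-filter: maximum RPKM strictly above 2 and coefficient of
  variation (sd/mean) strictly above 1; zero-mean genes are excluded since
  their CV is undefined.
* MDS: classical (metric) scaling of Euclidean distances between library
  expression vectors via eigendecomposition, with a residual stress
  statistic; an exactly Euclidean rank-k geometry is reproduced exactly.

# The synthetic generator

`generateAnnotation()` packs non-overlapping, stranded genes (1-4 kb, with
at least ~2.5 kb gaps when space allows) onto uniform-composition
chromosomes and places TEs, short TEs (< 500 bp) preferentially inside 2-kb
promoters — the genomic configuration whose methylation dynamics the
pipeline is designed to detect. `simulateMethylome()` simulates a
nucleotide sequence (GC 0.44, rice-like), derives every cytosine's context
on both strands from its trinucleotide, draws per-cytosine coverage from a
negative binomial with variance twice the mean (size = mu = 25 by default,
emulating uneven BS-seq depth), and draws methylated counts binomially
around per-context baselines (CG 0.40, CHG 0.10, CHH 0.05 — the plant
ordering, with mCHH on the few-percent scale of staged root tissue).

Planted differential windows are 50-bp tiles overlapping short promoter TEs
with at least 10 CHH sites. Over the stage series the expected CHH
proportion of a planted window runs linearly from baseline + 0.3 down to
baseline (hypo; 80% of planted genes by default) or the reverse (hyper).
Direction is assigned per host gene so all planted windows in one promoter
move together and a planted methylation-expression sign is well defined.
Both replicates of a stage share the same expected proportion.
`simulateExpression()` makes linked genes' log2 expression follow their
planted window's expected level — rescaled to 4 log2 units across the full
swing, sign per the ground truth — plus N(0, 0.5) noise per library;
unlinked genes are log-normal noise. The `GroundTruth` object records the
planted windows and the linked genes with their signs.

What the generator does *not* emulate: sequence composition bias and
methylation autocorrelation along the genome (baselines are uniform outside
planted windows, so between-bin level variance is smaller than in real
tissue), bisulfite non-conversion error, TE families, mappability gaps, and
expression mean-variance trends. Passing tests therefore demonstrate that
the procedures recover the signals they target under their stated
assumptions — not that the thresholds are optimal for any particular real
genome.

# Numerical and design choices

* Weighted levels pool counts; splitting sites into replicates and pooling
  again is exactly invariant.
* 100-kb bins (and 50-bp windows) are anchored at position 1 per
  chromosome; the final partial bin is kept. Global per-sample levels are
  reported genome-wide pooled (`sum(mc)/sum(cov)`), with the 100-kb
  distribution available alongside, since reported per-sample percentages
  are single numbers while box plots show distributions.
* CG sites on the two strands are counted independently (no CpG-pair
  merging).
* Metaplots scale each feature body to a fixed bin count by integer
  arithmetic and flip bin indices for minus-strand features, so a strand
  flip mirrors the profile exactly and pooled counts are conserved.
* The percent-change statistic is `100 * (before - after) / before`,
  positive for a decrease; the accompanying significance test is a
  two-proportion z-test on pooled methylated/total counts.
* The generator, control-window sampler and pipeline take explicit seeds
  and restore the caller's RNG state; a fixed seed fixes every output byte.

# Problem sizes used by the test suite

The suite exercises the pipeline end to end on compact genomes chosen so
the planted signals are recoverable with comfortable margins: a two-stage
1-Mb fixture with 200 planted hypo-CHH windows (delta 0.3, depth 25x per
replicate) for DMR recovery, nine-stage 0.4-Mb fixtures (60 genes, 30% of
them methylation-linked) for the correlation analysis, and an exhaustive
sweep of all 2x2 tables with totals up to 60 for the Fisher test. At these
sizes windowed sensitivity is essentially 1 and the null false-call rate is
well below 0.5% of windows, while unlinked-gene classification sits a
little under the method-inherent 3-4% discussed above.

# Worked example

```{r example, eval = FALSE}
library(rootMethylome)

cfg <- SimulationConfig(chromLength = 3e5, nGenes = 40, nTEs = 100,
                        plantedDMRCount = 40, seed = 11)
ann <- generateAnnotation(cfg)
sim <- simulateMethylome(ann, cfg)

weightedMethylation(sim$tracks[["S0_R1"]], "CHH")$level

ws <- windowCounts(sim$tracks[c("S1_R1", "S1_R2")],
                   sim$tracks[c("S0_R1", "S0_R2")],
                   annotationSeqlengths(ann), context = "CHH")
dmrs <- annotateDMRs(callDMRs(ws), ann)
summarizeDMRs(dmrs)

ctrl <- sampleControlWindows(annotationSeqlengths(ann), 2000, seed = 1)
compareLengthDistributions(
  associatedTELengths(dmrs, annotationTEs(ann)),
  associatedTELengths(ctrl, annotationTEs(ann)))$summary
```

Or, as one orchestrated run with tables and a manifest on disk:

```{r pipeline, eval = FALSE}
config <- pipelineConfig(simulation = cfg, outDir = "run1")
res <- runFullAnalysis(config)
res$percent_changes
```

# Known limitations

The caller tests pooled counts (no replicate dispersion model), reports
50-bp windows without merging, and its CHH difference threshold of 0.1 is
large relative to low-methylation tissues — all deliberate mirrors of the
procedure it implements. The correlation analysis is associative, not
causal, and its best-bin selection is a maximum over correlated tests (see
above). The generator's planted gradients are linear in stage index, which
is the easiest monotone signal to recover; non-monotone regulation would
require the signed-mode switch and different ground truth.
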
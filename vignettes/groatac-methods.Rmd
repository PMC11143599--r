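---
title: "Models and methods behind groatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind groatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`groatac` implements a regulatory-genomics workflow for studying
drug-induced chromatin and transcription dynamics in leukemia cell models:
calling active enhancers from strand-specific nascent transcription,
testing differential nascent activity, per-cell chromatin QC and motif
activity from scATAC-style fragment files, and chromatin-state-specific
signal aggregation. This vignette explains the models, the parameters that
matter, and the design decisions taken where the analysis recipe left
genuine choices open.

## Coordinate conventions and data containers

All region arithmetic uses 0-based half-open intervals (the BED
convention), held in plain data frames; overlap queries go through
`GenomicRanges`/`IRanges` internally. Nascent signal is carried as dense
per-base vectors per chromosome and strand (`stranded_coverage`);
minus-strand values are stored as non-negative magnitudes — the sign seen
in browser tracks is a display concern only. Single-cell data enter as
10x-convention 5-column fragment files (chrom, start, end, barcode,
duplicate count); duplicate multiplicity counts toward every metric.

## Enhancer calling from nascent transcription

Active enhancers produce short bidirectional transcripts (eRNAs). The
caller starts from accessibility peaks (ATAC/DHS), reduces each to its
midpoint, and extends by `flank` (default 500 bp, giving 1 kb candidate
regions). Candidates whose region overlaps a gene body with nonzero
sense-strand signal in the overlap, or any promoter, are excluded: their
signal is attributable to gene transcription. The promoter window is
upstream 1000 bp / downstream 500 bp of the TSS in the transcribed
orientation — a conventional choice; the recipe this implements does not
pin a promoter width.

**Strand balance.** Genuine intergenic enhancers show approximately equal
plus- and minus-strand eRNA. When the strand ratio exceeds ten-fold, the
stronger strand typically reflects read-through past an annotated
termination site, so only the weaker strand is trusted. We read the
ten-fold rule as a ratio of strand means (a difference reading is
dimensionally unstable) and symmetrize the effective signal of imbalanced
candidates to `2 x min(plus, minus)` so that effective counts stay on the
same scale as balanced candidates, whose effective signal is the plain
sum.

**Evidence filter.** A candidate is kept if its effective signal reaches
`min_cpm` counts-per-million in at least one sample *or* the region
intersects a histone-mark ChIP peak (H3K27ac/H3K4me1-style evidence).
Whether the cpm rule should demand one or two samples is ambiguous in the
source recipe; one sample is the default and the threshold is exposed.

**Nucleosome-free dips.** Within broad histone peaks (< 7.5 kb — wider
peaks are skipped, where the approach is known to degrade), the signal is
smoothed by a 50 bp moving average and local minima whose value falls
below half the lower flanking summit are reported as nucleosome-free
dips. The 0.5 valley-to-summit threshold and the ±100 bp dip window used
during cluster resolution are this package's choices; the dip operator is
otherwise unspecified in the recipe. Flat-bottomed valleys count once, at
their center.

**Cluster resolution.** Kept candidates within 500 bp of each other form
a cluster; the representative is the member overlapping best (most base
pairs) with an ATAC peak or a dip window, falling back to maximum
effective signal, with ties to the smaller coordinate. The 500 bp gap
quantifies "tightly clustered", which the recipe does not.

## Differential nascent activity

Genes are quantified on their bodies, sense strand only, with exonic
bases masked (mature-RNA contamination) and a per-base signal cap of 3
(suppressing PCR/alignment pileups). Enhancers are quantified with the
strand-balance rule (`strand_mode = "effective"`).

**Normalization** is median-of-ratios (RLE): the reference is the
per-feature geometric mean over samples (features containing zeros are
excluded from the reference), each sample's factor is its median ratio to
the reference, and factors are rescaled to geometric mean 1. Because
these factors already absorb depth, the GLM offset is `log(size factor)`
(the overall scale is absorbed by the intercept).

**The NB quasi-likelihood F-test** is authored here rather than delegated
to an existing implementation; acceptance is by operating characteristics,
the only verifiable surface. Per feature, a negative-binomial
log-linear model with one mean per condition is fitted at the *trended*
dispersion: method-of-moments dispersion estimates on normalized counts
are smoothed against log mean with non-robust lowess (robust iterations
would bias the trend below the mean of the right-skewed raw estimates).
Per-feature departures from the trend are carried entirely by the
quasi-dispersion — residual deviance over residual df — which is
moderated across features by empirical Bayes (`limma::squeezeVar`). The F
statistic is the contrast deviance drop divided by the moderated
quasi-dispersion, referred to an F distribution whose denominator df adds
the estimated prior df. Fitting at the trend keeps numerator and
denominator on the same scale; in null simulations (2000 features,
mu = 100, dispersion 0.1, 3 vs 3) the empirical type-I error at 0.05 is
0.047–0.053 with Kolmogorov–Smirnov distance to uniform below 0.04.
All-zero features are reported with p = 1 by convention.

**The any-change LRT** compares the per-condition-mean model to an
intercept-only model with per-feature empirical-Bayes-shrunk dispersions
(prior weight 20, floor 1e-6) and refers the deviance drop to a
chi-square with `conditions - 1` df. Significant genes (the convention is
FDR < 0.001) can then be clustered with `kmeans_profiles()`: k-means++
seeding, 25 restarts, fixed seed, k = 6 by default, labels renumbered by
descending cluster size. All multiple-testing correction is
Benjamini–Hochberg (`bh_fdr()`, a validating wrapper over the standard
step-up).

## Per-cell fragment QC

The nucleosome signal is the ratio of mononucleosome-sized fragments
(147–294 bp) to sub-nucleosomal fragments (< 147 bp); condensed,
mitotic-like chromatin shifts the fragment-length distribution toward the
mononucleosome band and raises this ratio. A cell with no sub-nucleosomal
fragments gets `Inf` (it fails the `< 10` QC cutoff, matching the
filter's intent for fully condensed profiles); a cell with no fragments
gets `NaN`. The metric can be restricted to one chromosome (`ns_chrom`)
for fidelity with pipelines that compute it on chr1; the toy genome
default is genome-wide.

TSS enrichment is defined here as an explicit, simple contract: each
fragment contributes two insertions (start and end−1); enrichment is the
mean insertion count in the central 101 bp of the TSS ± 2 kb window,
aggregated over all TSSs, divided by the mean count in the two outermost
100 bp flanks. Uniform coverage gives exactly 1.

Default QC cutoffs (all strict): in-peak fragments in (1000, 100000),
percent reads in peaks > 15, blacklist ratio < 0.05, nucleosome signal
< 10, TSS enrichment > 2. Variant runs that used a 50% in-peak cutoff are
supported by overriding `pct_in_peaks_min`.

## Motif deviation scores

The peaks × cells matrix counts insertions per peak, after discarding
peaks narrower than 10 bp and peaks detected in at most 1% of cells. For
motif *m* and cell *c*, the raw deviation is
`(observed − expected) / expected`, with the expectation assuming the
cell spreads its counts like the aggregate pseudo-cell (whose deviation
is 0 by construction; raw deviations are also invariant to scaling any
cell's depth). Each motif's raw deviation is standardized against `B = 50`
background peak sets, built by replacing every motif peak with a random
peak from the same GC decile × log-mean-accessibility decile bin; the
grid is capped so bins average at least four peaks, since singleton bins
would make the backgrounds degenerate. Background-matched random peak
sets score mean ≈ 0, SD ≈ 1 across cells, which is verified in the test
suite.

Cluster-specific motifs are called by Wilcoxon rank-sum of z-scores
(cluster vs rest) with the effect reported as a difference of mean
z-scores — deviations can be negative, so a literal fold change is
ill-defined — thresholded at 1.5 with BH FDR < 1e-4. The rank-sum test is
a vectorized normal approximation with tie and continuity corrections
(cross-checked against `wilcox.test`); exactness at very small clusters
(< ~10 cells) is approximate. Known-motif enrichment between region sets
uses Fisher's exact test with Haldane-corrected odds ratios, background
excluding the targets.

## Chromatin-state-specific aggregation

Per-cell counts are log1p-normalized (scale factor 1e4); each region is
tested state-vs-rest by the same rank-sum machinery with a log2 fold
change of means (+1 pseudocount). Regions with `|log2FC| >= 0.1` and BH
`q < 0.1` rank by absolute fold change into top-200 up and down lists per
state. Pseudobulk tracks sum fragment (or insertion) coverage over the
member cells of each state; signal matrices average per-base signal in
25 bp bins over ±1 kb (±2 kb for TF-occupancy-style profiles) around
region centers, with the center on the boundary between the two middle
bins, and `average_profile()` provides the companion histograms.

A statistical note: with the state-vs-rest test controlled at FDR 0.1,
label permutations on null data still produce at least one significant
call in roughly 10% of permutations — that is what FDR control at 0.1
means under a complete null, and the fold-change gate removes only the
small-effect part of it. The test suite documents this operating
characteristic.

## The synthetic-data generator

The generator plants ground truth that the pipeline must recover, sized
to run in seconds: 2 chromosomes × 2 Mb, 60 genes, 120 intergenic
enhancers, 80 decoy accessibility peaks, broad histone peaks (1–7 kb with
a central dip) over 60% of enhancers, and a blacklist covering 12% of
decoys. Features occupy disjoint slots, guaranteeing ≥ 2 kb clearance
between enhancers and genes. Nascent coverage is per-base Poisson —
background 1e-5 events/base/strand, gene bodies ~0.02 events/base on the
sense strand, enhancers ~300 counts spread over ±300 bp and split across
strands (50/50 balanced; 95/5 for the 10% imbalanced fraction that must
trip the ten-fold rule) — with region-level Gamma mixing (dispersion 0.1)
so that replicate samples are negative-binomially dispersed, as the
downstream test assumes. Two conditions with three replicates and planted
2–4-fold changes on 30% of features emulate a treatment time course at
desk scale.

Fragment files model three cell states × 200 cells × 2000 fragments:
65% of fragments in peaks, 15% at gene TSSs (so TSS enrichment is
meaningful), the rest uniform background; lengths mix a sub-nucleosomal
component (mean 75 bp, < 147) with a mononucleosomal one (mean 200 bp,
truncated to [147, 294]) at the cell's state-specific weight (0.3, 0.3,
0.8 — the third state models the condensed mitotic-like population).
State 2 carries a 2× multiplier on motif-M1 peaks (the planted
differentially active TF), and each state has 20 exclusive peaks at 3×
accessibility.

What the generator does **not** emulate: sequence content (GC is an
attribute, not a property of real sequence), mappability artifacts, real
fragment-length periodicity beyond two components, doublets, batch
effects, and peak-calling uncertainty (peaks are inputs). Passing tests
therefore demonstrate correctness of the computations under the stated
statistical structure, not robustness to every artifact of real
sequencing data.

## Numerical choices and degenerate inputs

Problem sizes in the test and acceptance runs — 2000-feature null and
power simulations, 600-cell fragment sets, 100 label permutations, the
2 × 2 Mb demo pipeline — were chosen so the whole validation executes in
a few minutes on a single core while keeping Monte-Carlo error well
inside the asserted bands. Other notable conventions: dispersion floor
1e-6; quasi-dispersion floor 1e-6 after moderation; k-means ties broken
by restart quality (total within-cluster SS); candidate regions clipped
at chromosome edges are dropped with a warning rather than truncated, so
all candidates share one width; zero-signal candidates are excluded
before any ratio is formed; empty fragment sets yield `NaN` metrics that
fail QC rather than erroring.

## Command-line use

The exported functions are the primary interface; a thin wrapper for
shell use ships at `inst/scripts/groatac-run.R` and runs the full
pipeline from a YAML configuration (`inst/extdata/demo_config.yaml` is a
commented example covering every stage block). `run_pipeline()` executes
simulate → call-enhancers → quantify → diffactivity → fragqc → motifdev →
aggregate, derives per-stage seeds from the global seed, and writes a
manifest with parameters, seeds and output checksums; identical
configurations reproduce byte-identical outputs.
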
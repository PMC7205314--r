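---
title: "Methods: from chimeric CLIP reads to a dynamic miRNA-target interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chimeric CLIP reads to a dynamic miRNA-target interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearclipr)
```

## What the package computes

`clearclipr` implements a complete analysis chain for chimeric Argonaute CLIP
(CLEAR-CLIP) sequencing experiments, in which a mature miRNA is ligated to its
target mRNA fragment inside the silencing complex, so that a single sequencing
read can carry both partners of an interaction. The chain is:

1. **Read preprocessing** — quality filter, 3' adapter trimming, removal of a
   degenerate 3-nt 5' barcode, collapse of identical reads, 16-nt length floor.
2. **Chimera calling** — locate a mature miRNA inside each read by local
   alignment, split off the flanking target candidate, map it to the
   transcriptome, discard rRNA/tRNA hits; reads without a miRNA but with a
   transcript hit are conventional CLIP reads.
3. **Peak calling** — pooled CLIP and chimeric-target intervals are clustered
   by overlap; a cubic spline locates each cluster's summit; a Poisson test
   against uniform placement flags significant Argonaute binding peaks.
4. **Interaction building** — chimeras sharing a miRNA and overlapping target
   sites merge into interactions, annotated with peak support.
5. **Duplex energetics** — a nearest-neighbor dynamic program scores the
   hybridization stability of each miRNA:target pair against a shuffled
   reassignment null.
6. **Motif analysis** — seed-match density around the ligation site, per-miRNA
   7-mer enrichment (ZOOPS counting, hypergeometric tests), and mapping of
   enriched motifs onto miRNA positions (registers) per time point.
7. **Dynamics** — peak heights normalized to mRNA abundance form an
   interaction-by-time-point matrix analyzed by z-normalization, a
   self-organizing map (SOM), stage correlations and hierarchical clustering.
8. **Perturbation validation** — Kolmogorov-Smirnov comparison of fold-change
   CDFs for targets vs non-targets, and translational efficiency (TE) from
   ribosome-footprint and mRNA counts.

Every stage is exercised end-to-end on synthetic libraries with planted ground
truth produced by the package's own generator, so all statistical claims in
the test suite are claims about recovery of known truth.

## The synthetic-data generator

The generator (`sim_config()`, `sim_reference()`, `sim_plant_interactions()`,
`sim_library()`, `sim_dataset()`) emulates the statistical structure that the
downstream analyses assume:

* **Read-class mix.** The default mix is 1.70% miRNA-mRNA chimeras, 77.07%
  CLIP-only mRNA reads, 10.30% miRNA-only reads and 10.96% structural ncRNA
  (normalized to sum to one), matching the composition reported for real
  chimeric CLIP libraries in mosquitoes and other organisms (chimeras are
  1-3% of reads).
* **Library layout.** Each read is a degenerate 3-nt barcode, an insert, and
  the Illumina 3' adapter `AGATCGGAAGAGCACACGTCT`, truncated at 100 nt.
  Quality strings are constant Phred 37; quality filtering is exercised by
  constructing low-quality reads directly in tests.
* **Planted sites.** Canonical sites embed the reverse complement of miRNA
  nucleotides 2-8 (which contains the nt 2-7 seed match), 3'-supplementary
  sites nt 13-19, central sites nt 9-15; seedless sites are rejection-sampled
  to contain no 6-mer complementary to miRNA nt 1-8. Registers are
  configurable.
* **Target fragments** follow a truncated normal (mean 42 nt, sd 10, minimum
  16 nt): chimeric reads in real libraries preferentially carry ~42-nt mRNA
  fragments. The site sits a configurable distance (default 20 nt, Gaussian
  jitter sd 3) from the ligation junction; miR-first and miR-last orientations
  are mixed 70:30 (the orientation split is not quantified in the source data,
  and only the miR-first excess direction matters downstream).
* **Stage activity.** Each interaction gets an activity profile peaked at one
  of the five time points (3, 30, 120 h post-eclosion; 24, 48 h post blood
  meal), scaled by a log-normal miRNA abundance weight — so chimera counts per
  miRNA track miRNA abundance, reproducing the abundance-frequency correlation
  seen in real data.
* **PCR duplicates** replicate the (barcode, insert) pair of a unique
  molecule. Substitution errors (default 0.5% per base) are applied to each
  unique molecule *before* duplication, i.e. they are modeled as
  amplification-stage errors shared by all duplicates; sequencer-stage errors
  on individual duplicates would make exact duplicate collapse impossible by
  construction, which is not how the degenerate-barcode collapse is meant to
  behave.
* **ncRNA decoys** are GC-rich random sequences rather than realistic rRNA:
  their only job is to make mis-mapping detectable.

What the generator does **not** model: realistic base composition, indels,
paired-end layout, isomiRs, secondary structure of targets, or cross-linking
biases. Passing tests therefore demonstrate correct recovery of planted
structure under idealized noise, not performance on real libraries.

## Alignment and E-values

The chimera caller uses a word-seeded Smith-Waterman local aligner
(blastn-like scoring: match +2, mismatch -3, gap open -5, gap extend -2)
written in C++. A read is only aligned against a miRNA if they share an exact
word (default 11 nt, the classic nucleotide-BLAST word size); transcriptome
mapping seeds on exact 12-mers and extends in a band around the seed diagonal.
E-values use the ungapped Karlin-Altschul formula with lambda solved
numerically for the scoring above (about 0.634) and K = 0.41, the tabulated
ungapped value for this scoring.

The E-value geometry matters. The miRNA screen treats each mature miRNA as
the query and the cleaned reads as the database (n = total read nucleotides),
as in the original protocol. Under that geometry the threshold E < 0.4
effectively requires about 14 matched bases in a typical library — chance
11-mer matches are rejected, which is what keeps chimera precision high while
an exact mature miRNA (score 44+) passes with E below 1e-4. Target mapping
treats the segment as the query and the transcriptome as the database.

Reads are classified into exactly one of `chimera`, `mirna_only`, `clip`,
`ncrna`, `unmapped`, `ambiguous`. A read with residuals on both sides of the
miRNA is ambiguous unless the shorter side is below 6 nt (linker slack);
residuals shorter than 16 nt on both sides make the read miRNA-only.
Multimapped segments (equal best score at distinct loci) stay in the chimera
table but are flagged and excluded from interaction building.

## Peak calling

Overlapping intervals (at least one shared base; abutting half-open intervals
do not merge) form clusters. The summit of a cluster is the global maximum of
a cubic spline fit to per-position coverage, evaluated on a 0.1-nt grid.
Short clusters (< 10 positions) use an interpolating natural spline; longer
ones use a smoothing spline whose smoothing parameter is the **largest** value
with residual sum of squares at most the number of positions (a binary search
on `spar`). This mirrors a smoothing budget of `s = n` and is deliberate: an
automatically tuned (GCV) spline chases single-position wiggles on
plateau-shaped coverage and misplaces summits by 10-20 nt, while the budgeted
spline recovers planted summits within 5 nt in ~97% of cases at the
generator's placement jitter. Constant coverage puts the summit at the
interval midpoint; reported heights are floored at the observed maximum depth.

Significance is a Poisson upper tail under uniform placement within the
transcript: lambda = (transcript read total) x (cluster width / transcript
length), significant when p < 0.01. The empirical type-I rate of this test on
data-defined clusters under uniform placement is about 0.9% (Monte Carlo in
the test suite), i.e. slightly conservative at the nominal level.

## Duplex energetics

`duplex_mfe()` minimizes, over all non-crossing intermolecular pairings
(miRNA 5'→3' against target 3'→5'), the sum of a duplex initiation penalty
(+4.09 kcal/mol), nearest-neighbor stacking energies, bulge/internal-loop
penalties (by total loop length, capped at `max_loop = 15`), and terminal
AU/GU penalties (+0.45 per helix end). The Watson-Crick block of the stacking
table is the standard 37 °C nearest-neighbor set; G:U wobble stacks use a
simplified uniform parameterization (-1.1 kcal/mol with one wobble pair,
-0.4 with two). A duplex whose optimum is above 0 is reported unstable
(`mfe = 0`, no pairing). Ties break toward more paired bases, then leftmost.

The package does not promise numerical agreement with any external
hybridization tool; the accuracy surface is internal: the compiled dynamic
program must agree exactly with `duplex_mfe_reference()`, an independently
written pure-R memoized recursion (top-down, opposite direction, separate
code path), which in turn is validated against exhaustive enumeration of all
non-crossing pairings on very short sequences. Scored target sequences are
the site interval extended by ±10 nt of transcript context (RNase trimming
truncates true sites); the flank is a configuration knob.

The null model (`shuffled_null()`) reassigns every target to a uniformly
chosen *different* miRNA (a derangement with respect to miRNA identity),
preserving both the multiset of targets and the multiset of miRNAs. The
energy gap is the difference in median and mean MFE between real and shuffled
assignments with a two-sided label-permutation p-value (default 10,000
permutations, seeded).

## Motif analysis

External motif discovery tools are replaced by an explicit, fully specified
procedure: ZOOPS k-mer counting (a target counts at most once per k-mer),
hypergeometric enrichment against a background of other miRNAs' targets
sampled at five times the target count, and Bonferroni correction over all
4^k k-mers. miRNAs with fewer than 30 unique targets at a time point are
skipped (reported as NA columns). Motifs are retained when the corrected
p-value is below 0.05, the best register matches at least 6 of 7 positions
of the reverse-complemented miRNA, and the per-column information content of
the instance profile is at least 1.5 bits (for exact k-mer instances this is
2 bits by construction; the filter is kept for forward compatibility with
degenerate matching). An opaque "confidence" filter used by one upstream
tool has no public closed form and is deliberately replaced by the
corrected-p filter. A separate cross-stage comparison threshold
(50 unique interactions) is exposed as a configuration knob; the 30-target
and 50-interaction thresholds coexist in the source material and are both
kept configurable rather than reconciled.

Registers translate k-mer offsets along the reverse-complemented miRNA into
1-based miRNA 5'→3' positions, so a k-mer equal to the reverse complement of
nt 2-8 reports register 2-8. The usage matrix gives, per miRNA position and
time point, the proportion of that miRNA's targets carrying a retained motif
whose register covers the position — planted 1-nt register shifts between
time points appear as 1-position shifts between heatmap columns.

Seed-match density counts occurrences of the reverse complement of miRNA
nt 2-7 within ±100 nt of the ligation site (the fragment boundary that was
ligated to the miRNA), normalized per chimera, with the shuffled reassignment
as control.

## Dynamics

Only peak-supported interactions enter the dynamics matrix. Interactions are
built per time point and then joined across time points on (miRNA,
transcript, overlapping site). Each cell is peak height divided by the
transcript's mRNA abundance at that time point, floored at 0.1 abundance
units to avoid division blow-ups; abundance units are taken as-is from the
expression table (the ratio is unit-agnostic). A log-ratio variant is
available via `log_ratio = TRUE`; the plain ratio is the default.

The SOM is a batch Kohonen map: codebook seeded from random rows, Gaussian
neighborhood, learning rate decaying linearly, best-matching-unit
assignment, all deterministic under the seed. The neighborhood radius decays
linearly from 3/4 of the grid span to 2/5 of it (floored at 1). The final
radius is kept proportional to the grid on purpose: with a final radius of 1
a batch SOM spreads each temporal program over a number of tiles proportional
to its membership (the quantization magnification effect), which scatters
planted programs beyond compact neighborhoods; a grid-proportional final
radius keeps same-program interactions within a Chebyshev distance of ~2
tiles while preserving the topographic ordering (adjacent tiles remain ~3-4x
more similar than random tile pairs). The production-scale default grid is
26x25 as in gene-expression dynamics inspectors; tests use 8x8, matched to
their problem size of a few hundred interactions. Discrete temporal programs
are extracted by `som_program_cut()`: k-medoids on tile mean profiles,
occupancy-weighted (each interaction is represented by its tile's mean), so
sparse boundary tiles cannot distort the cut — the unweighted cut was
unstable across seeds.

Stage correlations are Pearson correlations between time-point columns of
the (unstandardized) matrix; zero-variance columns give NA. Hierarchical
clustering of annotated subsets uses average linkage on Euclidean distances
between z-normalized rows, with rows sorted by id first so the tree is
invariant to input order; dendrograms export to Newick.

## Validation statistics

`cdf_compare()` is a two-sample Kolmogorov-Smirnov test on log2 fold-changes
of disjoint transcript sets, returning the CDF curves for plotting.
`translational_efficiency()` normalizes ribosome-footprint and mRNA count
tables separately by median-of-ratios size factors (cross-checked against the
DESeq2 implementation in the tests), brings both assays to a common library
scale by dividing each normalized matrix by its mean column total, and
reports TE = normalized ribosome occupancy / normalized mRNA abundance per
transcript and sample. Transcripts with fewer than 10 raw counts in every
sample of either assay are dropped (the floor is a documented choice; the
source material states none).

Two numerical caveats are documented rather than hidden. First,
median-of-ratios normalization with a substantial one-directional set of
shifted transcripts (15% of transcripts at 2x) absorbs a few percent of the
planted shift into the size factors; the recovered raw target median is
~1.85x rather than 2x. Referencing the target median against the non-target
median removes this shared bias and recovers the planted fold within a few
percent, so effect sizes should be read against the background, which is how
the test suite and the acceptance script report them. Second, TE's absolute
scale depends on the common-library anchoring; ratios of TE between
conditions or gene sets are the meaningful quantities.

## Problem sizes and determinism

The test suite and the acceptance script run the full chain on a 50,000-read
library (the generator's default, with the paper-like class mix, 0.5%
substitution errors), a 500-transcript uniform-placement null for peak
calibration (~9,000 clusters), 100 planted-summit cases, 250 random duplex
pairs against the reference implementation, a 500-interaction canonical
interactome with 10,000 permutations, 40 miRNAs x 40 targets for register
recovery, a 400 x 5 profile matrix on an 8x8 SOM, 100 fold-change
simulations, and a two-time-point pipeline determinism check. These sizes
were chosen so each property is measured with comfortable statistical margin
while the whole suite completes in a few minutes.

All randomness flows through explicit seeds; library code never perturbs the
caller's RNG state (seeding is scoped and restored). `run_all()` writes only
deterministic outputs (no timestamps), so rerunning with the same inputs and
seed is byte-identical — verified file-by-file in the tests.

## Interfaces

The package is used from R: tibbles in, tibbles out, `plot_*()` /
`autoplot()` ggplot2 helpers for each result type, and broom-style `tidy()` /
`glance()` methods for fitted objects (`ccl_som`, `ccl_energy_gap`,
`ccl_cdf`). `run_all()` orchestrates the full chain over a dataset directory
and writes TSV/JSON outputs with a manifest recording the configuration,
seeds and package version; it is the single entry point a pipeline wrapper
would call, and together with the exported stage functions it covers the
orchestration surface without a separate shell executable.

## Known limitations

* The aligner is transcript-space only: no spliced/genome alignment, no
  reverse-strand miRNA search (chimeras ligate the mature miRNA sense-strand).
* E-value parity with any specific BLAST version is not promised — only the
  threshold semantics (E < 0.4) under the documented Karlin-Altschul model.
* The energy model is a compact nearest-neighbor parameterization, not a
  drop-in replacement for specialized hybridization tools; G:U stacks are
  simplified, and target accessibility/intramolecular structure is ignored.
* Motif analysis is exact-k-mer based; position-weight-matrix refinement and
  isomiR-aware register correction are out of scope.
* The SOM is a compact batch implementation for gridding temporal profiles,
  not a reimplementation of any specific visual-analytics tool.
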
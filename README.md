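# clearclipr

Analysis of **chimeric Argonaute CLIP (CLEAR-CLIP) sequencing** in R: from raw
FASTQ reads to a clustered, peak-supported miRNA–mRNA interactome with duplex
energetics, seed/motif registers and temporal dynamics.

In a CLEAR-CLIP experiment, the miRNA and its target mRNA fragment are ligated
together inside the Argonaute silencing complex, so a single sequencing read —
a *chimera* — directly reports which miRNA bound which site. Libraries also
contain conventional CLIP reads (Argonaute-protected mRNA fragments),
miRNA-only reads and structural ncRNA. `clearclipr` implements the complete
computational chain for such libraries, for researchers studying miRNA
targeting rules and stage-specific regulation (e.g. across insect reproductive
time courses):

* **Read prep** — quality filter, 3′ adapter trim, degenerate 3-nt barcode
  (UMI) removal, identical-read collapse, 16-nt floor.
* **Chimera calling** — word-seeded Smith–Waterman in transcript space
  (match +2 / mismatch −3, affine gaps), ungapped Karlin–Altschul E-values with
  threshold E < 0.4; each read is classified as
  chimera / miRNA-only / CLIP / ncRNA / unmapped / ambiguous.
* **Peak calling** — overlap clustering of pooled CLIP + chimeric-target
  intervals, cubic-spline summits, Poisson significance against uniform
  placement (λ = N·w/L, p < 0.01).
* **Interactions** — chimeras with the same miRNA and overlapping sites merge;
  peak support is attached by ≥ 1-nt overlap with a significant peak.
* **Duplex energetics** — intermolecular nearest-neighbor minimum free energy
  by dynamic programming (initiation + stacks + loop penalties + terminal
  AU/GU), compared against a shuffled miRNA-reassignment null with a
  permutation test.
* **Motifs** — seed-match (reverse complement of miRNA nt 2–7) density around
  the ligation site; per-miRNA 7-mer enrichment (ZOOPS counting,
  hypergeometric test, Bonferroni over 4⁷); register mapping onto the miRNA;
  per-time-point usage matrices.
* **Dynamics** — peak heights normalized to mRNA abundance, z-scores, batch
  self-organizing map gridding, stage correlations, hierarchical clustering.
* **Validation** — Kolmogorov–Smirnov comparison of fold-change CDFs for
  targets vs non-targets; translational efficiency (ribosome occupancy /
  mRNA abundance) from count tables.

A first-class **synthetic-data module** generates toy transcriptomes,
mirnomes, planted interactions and FASTQ libraries with known ground truth
(read-class mix ≈ 1.7 % chimeras / 77 % CLIP / 10 % miRNA-only / 11 % ncRNA,
miR-first and miR-last orientations, PCR duplicates under the degenerate
barcode, stage-specific activity), so every stage is testable offline.

## Worked example

```r
library(clearclipr)
library(dplyr)

cfg   <- sim_config(n_transcripts = 150, n_mirnas = 30, n_interactions = 150,
                    n_reads = 20000, rng_seed = 42)
truth <- sim_plant_interactions(sim_reference(cfg), cfg)
lib   <- sim_library(truth, "24hPBM", cfg)

prep  <- prep_reads(lib$reads)
calls <- call_chimeras(prep$reads, truth$reference$mirnas,
                       truth$reference$transcripts, truth$reference$annotation)
composition_summary(calls)$classes
#> # A tibble: 5 × 3
#>   class          n fraction
#>   <chr>      <int>    <dbl>
#> 1 chimera      327  0.0164
#> 2 clip       15484  0.774
#> 3 mirna_only  2061  0.103
#> 4 ncrna       2109  0.105
#> 5 other         19  0.00095
```

The composition recovered after classification matches the generator's
configured mix (1.70 / 77.07 / 10.30 / 10.96 %). Peaks and interactions:

```r
peaks <- call_peaks(calls$clip, calls$chimeras, truth$reference$transcripts)
ints  <- build_interactions(calls$chimeras) |> attach_peak_support(peaks)
head(ints[, c("interaction_id", "unique_reads", "region", "peak_supported")], 5)
#> # A tibble: 5 × 4
#>   interaction_id      unique_reads region peak_supported
#>   <chr>                      <int> <chr>  <lgl>
#> 1 miR-003|TX0031|1992            2 3UTR   TRUE
#> 2 miR-003|TX0070|1377            2 CDS    TRUE
#> 3 miR-004|TX0105|1702            2 3UTR   TRUE
#> 4 miR-004|TX0131|639             1 CDS    TRUE
#> 5 miR-006|TX0021|227             2 CDS    FALSE
```

Each interaction is one clustered binding site (`mirna|transcript|start`,
0-based), `unique_reads` counts distinct collapsed chimeras supporting it, and
`peak_supported` marks overlap with a significant Argonaute binding peak.
Duplex stability of real vs shuffled miRNA–target assignments:

```r
model   <- default_energy_model()
mir_seq <- setNames(truth$reference$mirnas$sequence, truth$reference$mirnas$mirna_id)
pairs   <- tibble(interaction_id = ints$interaction_id, mirna_id = ints$mirna_id,
                  mirna_seq = unname(mir_seq[ints$mirna_id]),
                  target_seq = site_sequences(ints, truth$reference$transcripts))
real <- duplex_energies(pairs, model)
nul  <- shuffled_null(pairs, seed = 1)
nul$mirna_seq <- unname(mir_seq[nul$mirna_id])
glance(energy_gap(real$mfe, duplex_energies(nul, model)$mfe, seed = 1))
#> # A tibble: 1 × 6
#>   delta_median delta_mean    p_mean n_real n_null n_perm
#>          <dbl>      <dbl>     <dbl>  <int>  <int>  <dbl>
#> 1         -4.1      -3.72 0.0001000     65     65  10000
```

Real interactions are ~4 kcal/mol more stable (more negative minimum free
energy) than randomly re-assigned pairs — the planted complementarity is
energetically visible, and the permutation p-value is at its floor of 1/(n+1).
`run_all(input_dir, out_dir, seed)` chains every stage over a dataset
directory written by `sim_dataset()` and emits TSV/JSON outputs plus a
manifest; reruns with the same inputs and seed are byte-identical.

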
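# clonospace

Spatial T-cell receptor (TCR) repertoires from long-read spatial
transcriptomics.

## What problem this solves

Array-based spatial transcriptomics tags each cDNA with a 16 nt spot
barcode and a 12 nt UMI; long-read sequencing of target-enriched TCR cDNA
spans the entire V(D)J rearrangement, including the CDR3 loop that
identifies a T-cell clone. The catch is the ~4–5% per-base error rate of
uncorrected long reads, which destroys true CDR3s and fabricates spurious
clonotypes. `clonospace` implements the full computational path from raw
reads to spatial clone statistics for researchers analysing such
libraries:

1. **Demultiplexing** — the Read 1 adapter anchors barcode and UMI
   extraction (edit distance ≤ 4 on the anchor, ≤ 2 on the barcode);
   UMIs are deduplicated with the *directional* algorithm
   (`u` absorbs `v` iff Hamming(u, v) = 1 and count(u) ≥ 2·count(v) − 1).
2. **Reorientation / splitting** — strand restoration and adapter-fusion
   splitting, trimming all synthetic sequence.
3. **V-J-C annotation** — local affine alignment against segment
   references; CDR3 = conserved Cys codon up to the J Phe/Trp-Gly motif.
   External AIRR Rearrangement files are accepted as a bypass.
4. **Consensus error correction** — reads grouped by (V, C), clustered by
   k-mer Jaccard similarity with CDR3-aware refinement, and replaced by an
   iterative align-and-vote consensus; success measured as
   (mismatches + indels) / alignment columns against constant segments.
5. **Clonotypes** — CDR3 amino-acid sequences merged at Levenshtein
   distance ≤ 1 (`lev(x, y) < 2`); per-spot counts normalised by UMIs per
   cell, `UMI_c(b) = total_umis(b) / n_cells(b)`.
6. **Spatial statistics** — Delaunay spot graph; per-clone **clonality
   index** (mean over occupied spots of `m_b = |NN_b ∩ support|`, the
   Delaunay neighbours sharing the clone); per-spot **CDR3 diversity
   index** `DI = mean_j mean_{k≠j} lev(CDR3_j, CDR3_k)`; classification of
   spots into expansion / diversity niches.
7. **Ecosystem analyses** — cell-level Delaunay graphs, cell-type-specific
   expression enhancement (`e_g = avg_log2FC_g + 1`), clone × state
   matrices (`f(s, n) = s` if `n = 1`, else `Σ s_i`), composite
   cytotoxic/exhausted spot scores, and receptor–ligand ranking by
   spatial Kullback–Leibler divergence (top 100, ascending).

A seeded synthetic-data generator (hexagonal lattices, planted expanded
vs dispersed clones, configurable substitution/insertion/deletion error
channel) makes every stage testable end to end without external data.

## Worked example

```r
library(clonospace)

run <- run_pipeline(list(seed = 42,
                         simulate = list(n_spots = 100, n_clones = 20)),
                    quiet = TRUE)
run
#> <clonospace_run>
#>   reads_emitted         443
#>   reads_demultiplexed   389
#>   inserts               438
#>   inserts_annotated     438
#>   reads_corrected       438
#>   records_filtered      111
#>   clones                20
#>   error rate: 4.22% -> 0.02%
```

The waterfall counts reads surviving each stage: 443 simulated reads, 389
demultiplexed (87.8% — barcodes beyond 2 edits stay unassigned), 438
oriented inserts all annotated and corrected, 111 (barcode, CDR3) records
after UMI collapse and filtering, merging into exactly the 20 planted
clonotypes. Consensus correction brings the mean per-read error rate
measured against the constant segments from 4.22% to 0.02%.

```r
head(run$clone_stats, 5)
#>   clone_id n_spots clonality_index clonality_sum
#> 1 CL0001         4           0.5               2
#> 2 CL0002         6           0.333             2
#> 3 CL0003         7           1.71             12
#> 4 CL0004         3           0                 0
#> 5 CL0005         7           3.14             22

table(run$spot_metrics$label)
#> ambiguous expansion      none
#>        22        47        31
```

`CL0005` occupies 7 spots with a clonality index of 3.14 — its spots
average three co-clonal Delaunay neighbours, a locally expanded clone —
while `CL0004`'s three spots are mutually non-adjacent (index 0,
dispersed). Spot labels summarise the same information per niche.
`plot_spot_map()`, `plot_clone_abundance()` and `autoplot()` on the error
report draw the corresponding figures, and `tidy()`/`glance()` return the
long and one-row summaries of clone tables and error reports.

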
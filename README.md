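# tadcliques

Topologically associating domains (TADs) do not only fold locally: subsets
of TADs on the same chromosome engage in significant long-range contacts
with one another, and when three or more linearly non-contiguous TADs
interact *pairwise*, they form a **TAD clique** — a higher-order,
heterochromatin-leaning assembly that links domain-scale folding to
compartment-scale organization. `tadcliques` is an R package for finding and
characterizing such cliques in binned intra-chromosomal Hi-C contact maps.
It is written tidyverse-style: tabular inputs and outputs are tibbles,
results chain with the pipe, fitted objects have `tidy()`/`glance()`
methods and `autoplot()` views.

## What the package computes

Starting from a raw contact map (HiC-Pro style sparse triplets plus a bin
BED), the pipeline runs:

1. **TAD calling** — a γ-parameterized dynamic program. A candidate domain
   over bins *k..l* (length *d* = *l* − *k* + 1) is scored
   `q_γ(k, l) = s(k, l) / d^γ − μ_γ(d)`, where `s(k, l)` sums contacts inside
   the window and `μ_γ(d)` is the chromosome-wide mean of `s / d^γ` over all
   length-*d* windows. The segmentation maximizing the sum of
   positive-quality domains is found by dynamic programming
   (`OPT(l) = max_k { OPT(k−1) + max(q_γ(k, l), 0) }`), with uncovered bins
   emitted as gap segments so the output tiles the chromosome. Default
   γ = 1.2. Published TAD calls can be supplied instead via
   `read_segmentation()`.
2. **Interaction testing** — contacts are aggregated to TAD level and every
   eligible (linearly non-contiguous) TAD pair is tested under a Fisher
   non-central hypergeometric model with pmf
   `P(X = y) ∝ C(n_a, y) · C(N − n_a, n_b − y) · ω^y`, where `n_a`, `n_b`
   are the TADs' total contact counts, `N` the chromosome total, and
   `ω = E_ab · N / (n_a · n_b)` centers the test on the distance-decay
   expectation `E_ab`. P-values are Benjamini–Hochberg adjusted (FDR < 1%)
   and pairs must additionally show ≥ 5-fold observed/expected enrichment.
3. **Clique enumeration** — significant pairs become edges of a TAD graph;
   all maximal cliques are enumerated with Bron–Kerbosch (with pivoting).
   Each TAD gets its degree, maximal clique size *k*, the ratio
   `k / (degree + 1)`, and a size category (singleton, binary, clique_3 …
   clique_8plus).
4. **Characterization** — aggregate 25 × 25 intra-TAD contact heatmaps
   (nearest-neighbor resize, element-wise mean), convergent CTCF motif
   orientation at boundaries with exact binomial enrichment per category,
   repeat-class coverage fractions, clique vs non-clique expression
   (Kolmogorov–Smirnov), and best subcompartment overlap by Jaccard index.
5. **Cross-cell-type comparison** — cliques are matched between cell types
   by maximal base-pair Jaccard index of their footprints and the resulting
   profile matrix is clustered with k-means (k = 8 by default).

A seeded synthetic-data generator (`sim_config()` +
`simulate_contact_map()`, `simulate_ctcf_motifs()`,
`simulate_annotations()`) produces ground-truthed datasets with power-law
distance decay, block-enriched TADs of 0.2–1 Mb, planted clique edges,
boundary CTCF motifs depleted in clique TADs, LINE enrichment and lowered
expression inside clique TADs — so the whole pipeline is testable without
any downloads.

## Worked example

```r
library(tadcliques)
library(dplyr)

sim <- sim_config(seed = 1) |> simulate_contact_map()
sim
#> <tad_sim> 67 TADs (16 in planted cliques), 41 planted clique edges
#> <contact_map> chrS: 800 bins @ 50000 bp, 143434 non-zero pairs, total count 1,109,794

seg <- call_tads(sim$map, gamma = 1.2)

pairs <- sim$map |>
  aggregate_to_tads(seg) |>
  call_significant_interactions(fdr = 0.01, min_fold = 5)
summarise(pairs, tested = n(), significant = sum(significant))
#>   tested significant
#> 1  22155         337

graph <- build_tad_graph(pairs, nodes = seg$tad_id[seg$is_domain])
stats <- assign_clique_stats(graph)
count(stats, category)
#>   category         n
#> 1 singleton      163
#> 2 clique_3         7
#> 3 clique_5        18
#> 4 clique_7         1
#> 5 clique_8plus    23

planted_edge_recovery(pairs, seg, sim)
#>   precision recall n_called n_planted
#> 1         1      1       41        41
```

The simulated 40 Mb chromosome carries cliques of sizes 3, 5 and 8 planted
over 16 TADs. The caller over-segments the planted domains (212 called
domains for 67 planted), but every planted boundary is found, 337 TAD pairs
pass the FDR and fold filters, and after mapping called domains back to the
planted ones all 41 planted clique edges — and nothing else — are
recovered. The `category` table counts called TADs by the size of the
largest maximal clique they belong to; `stats$ratio` is the
clique-size-to-degree statistic `k / (degree + 1)` (exactly 1 for
singletons, e.g. 5/(7+1) = 0.625 for a TAD of degree 7 in a 5-clique).

`run_pipeline(pipeline_config(out_dir = "out", seed = 1))` performs all the
stages above, writes every intermediate as plain TSV/BED and records a JSON
provenance manifest; see the methods vignette
(`vignettes/tad-cliques.Rmd`) for the model details and design choices.

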
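# dpgnet

Functional network analysis of divergently paired genes (DPGs) in R.

DPGs — also called bidirectional or head-to-head gene pairs — are adjacent
genes on opposite strands whose transcription start sites (TSSs) face away
from each other within ±1 kb, typically sharing a promoter. About a tenth of
human genes are organised this way, and the interesting question is not
whether the two members do the *same* thing, but how the pairs stitch
*different* cellular functions together. `dpgnet` implements that analysis
end to end:

* **Pair calling** — identify DPGs from a gene coordinate table (BED/GFF3;
  0-based half-open, TSS = `start` on `+`, `end − 1` on `−`). A pair requires
  a signed TSS distance `d = tss(+) − tss(−)` strictly inside
  `(−1000, 0) ∪ (0, 1000)`; each gene joins at most one pair (nearest TSS
  wins, lexicographic tie-break), plus per-chromosome hypergeometric
  enrichment of DPG genes.
* **GO semantic similarity** — per namespace, Schlicker's relevance kernel

  `sim(t₁, t₂) = max over common ancestors a of [2·IC(a) / (IC(t₁) + IC(t₂))] · (1 − p(a))`

  with `IC = −ln p` from annotation frequencies, combined over two genes'
  term sets by `rcmax.avg` (mean of all row and column maxima), and compared
  between DPG pairs and 100,000 random gene pairs by a two-sample
  Kolmogorov–Smirnov test, with paralog-family exclusion.
* **Set network** — functional gene-set collections filtered to size > 5 and
  mutual overlap < 80%; an *interaction map* whose edges mark set pairs
  bridged by a DPG pair (one member in each set's exclusive part), retained
  at interaction rate > 0.07 (`rate = n_bridging / min(|A|,|B|)`); module
  detection by greedy cohesiveness growth
  `f(V) = w_in / (w_in + w_bound + p·|V|)` with multi-pass seeding and
  Simpson-coefficient merging (a ClusterONE-style procedure).
* **Perturbation scores** — moderated differential expression (closed-form
  empirical-Bayes variance squeeze), gene scores `−log10(p)`, the absolute
  pathway score `(Q1 + Q2 + Q3)/3` of the DPG members' scores with levels
  0–5, and a relative pathway score: the fraction of 10,000 equal-size
  random gene sets the observed score strictly exceeds, again binned into
  levels 0–5. Plus pair-correlation quartile summaries, tissue-variance
  bins, and housekeeping-gene calling.
* **Synthetic data** — seeded generators for genomes with planted
  head-to-head pairs, layered ontology DAGs with a tunable within-pair
  annotation-overlap probability per namespace, term-derived gene-set
  collections, and log2 expression matrices with planted differential,
  DPG-specific, uniform, housekeeping and tissue-specific structure — so
  every stage is testable against known ground truth without downloads.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for the main result types.

## Worked example

```r
library(dpgnet)

# a synthetic genome emulating the human DPG table composition
genome <- sim_genome(seed = 11)           # 17,280 genes, 864 planted pairs
pairs  <- find_dpgs(genome$genes)         # window = 1000 bp
count_distance_classes(pairs)
#> # A tibble: 1 × 4
#>   n_pairs n_genes n_positive n_negative
#>     <int>   <int>      <int>      <int>
#> 1     864    1728        682        182
```

864 pairs (1,728 genes), 682 at positive and 182 at negative TSS distance —
the caller recovers the planted composition exactly. Similarity, on a
smaller run:

```r
res <- run_dpg_pipeline(seed = 2, n_background = 3000, n_perm = 500)
print(tidy(res$similarity)[, c("namespace", "dpg_mean", "background_mean", "ks_p")],
      digits = 3)
#> # A tibble: 3 × 4
#>   namespace dpg_mean background_mean  ks_p
#>   <chr>        <dbl>           <dbl> <dbl>
#> 1 BP           0.136           0.133 0.328
#> 2 CC           0.356           0.128 0
#> 3 MF           0.281           0.129 0
```

With the generator defaults (planted overlap probability q = 0.9 for CC,
0.6 for MF, 0.1 for BP), cellular-component and molecular-function
similarity of DPG pairs is strongly right-shifted against random pairs
while biological process is statistically indistinguishable — the
qualitative contrast the method is built to detect. `glance(res$network)`,
`tidy(res$modules)` and `res$pathway_scores` expose the interaction map,
its modules and the per-set absolute/relative perturbation levels.

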
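---
title: "Methods: divergently paired genes and their functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergently paired genes and their functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpgnet)
```

Divergently paired genes (DPGs) are adjacent genes on opposite strands whose
transcription start sites face away from each other within a kilobase, so the
two members usually share promoter sequence. The package asks what that
arrangement does functionally: whether the two members of a pair do similar
things, and how the pairs, taken together, bridge different functional gene
sets into modules. This vignette documents the models, the conventions, and
the choices made where the problem is genuinely underdetermined.

## Pair calling

Coordinates are 0-based and half-open (the BED convention) throughout; the
TSS is `start` for a plus-strand gene and `end - 1` for a minus-strand gene.
The signed TSS distance of a pair is `tss(plus) - tss(minus)`: positive when
the two 5' ends diverge cleanly, negative when they overlap. A DPG requires
the distance to lie strictly inside `(-1000, 0)` or `(0, 1000)` base pairs;
a distance of exactly 0 or ±1000 is excluded because both defining intervals
are open.

Two conventions are needed that the problem statement leaves open:

* **One-to-one matching.** A gene may have several opposite-strand
  neighbours inside the window, but a gene can belong to only one pair.
  Candidates are accepted greedily by smallest absolute TSS distance, ties
  broken by lexicographic gene id — deterministic and order-invariant (the
  test suite shuffles input rows to prove it).
* **Adjacency.** By default no third gene's TSS may lie strictly between
  the two member TSSs (`require_adjacent = FALSE` disables this).

Chromosome enrichment of DPG genes is a per-chromosome hypergeometric tail
test against the genome-wide gene pool — gene counts are the density
normaliser, chromosome length enters only through them — with the smaller
tail reported as the direction and Benjamini–Hochberg adjustment across
chromosomes.

## GO semantic similarity

Similarity is computed per namespace from an `is_a` DAG and an annotation
corpus (IEA-evidence annotations are kept by default; a flag drops them).
Term probability `p(t)` is the fraction of namespace-annotated genes
annotated to `t` or any descendant; information content is `IC = -ln p`
(natural log — the IC ratio below is base-free, and `1 - p` needs the same
`p` either way). The term kernel is Schlicker's relevance similarity

$$\mathrm{sim}(t_1,t_2)=\max_{a\,\in\,\mathrm{anc}(t_1)\cap\,\mathrm{anc}(t_2)}
\frac{2\,\mathrm{IC}(a)}{\mathrm{IC}(t_1)+\mathrm{IC}(t_2)}\,\bigl(1-p(a)\bigr),$$

a Lin-style ratio damped by `1 - p` of the common ancestor, which keeps
shallowly annotated genes from scoring spuriously high. Two genes are
compared through the matrix of kernel values over their *direct* annotations
(ancestors enter only inside the kernel), combined by `rcmax.avg`: the mean
of all row maxima and column maxima. Genes with no non-root annotation in a
namespace are *undefined*, excluded from distributions and counted — scoring
them 0 would fabricate a left peak.

DPG scores are compared against uniformly sampled random distinct-gene pairs
(100,000 by default) with a two-sample Kolmogorov–Smirnov test using the
asymptotic p-value; at the hundreds-to-thousands of observations involved
the exact small-sample computation would change nothing. Same-family
(paralog) pairs can be excluded via a user-supplied family map, since a
handful of tandem-duplicate pairs (histones, in the human data) otherwise
dominate the high-similarity tail.

## The DPG-bridged set network

Functional collections are filtered to sets of more than 5 genes whose
mutual Simpson overlap `|A∩B| / min(|A|,|B|)` stays below 0.8. The filter
scans sets in descending size order (ties by name): the original chart order
of the source data is unrecoverable, and a fixed order makes the filter
reproducible.

A DPG pair *bridges* sets A and B when one member lies in `A \ B` and the
other in `B \ A`; pairs falling inside the intersection say nothing about
coupling between the sets and are not counted. The interaction rate divides
the bridging-pair count by `min(|A|,|B|)` — the same min-normalisation as
the overlap rate, keeping the two maps on one scale and the rate in [0, 1];
a geometric-mean denominator is available as a sensitivity knob, and the
convention is recorded in every output. Edges are retained when the rate
*strictly* exceeds the cutoff (interaction 0.07, overlap 0.30 by default).

Modules are found by greedy cohesiveness growth. For a node group V with
internal edge weight $w_{in}$ and boundary weight $w_{bound}$,

$$f(V)=\frac{w_{in}}{w_{in}+w_{bound}+p\,|V|},$$

with penalty `p = 2` (the conventional default; exposed). Seeds are taken in
decreasing weighted-degree order; single-node additions or removals are
applied while `f` strictly increases (ties broken by node name); seeding
continues from uncovered nodes until none grows ("multi-pass"). Grown groups
whose Simpson coefficient reaches 0.8 are merged transitively (connected
components of the overlap graph), groups below 3 nodes are dropped, and each
module is scored by a one-sided Mann–Whitney test of internal versus
boundary edge weights (`NA` for isolated modules, which have no boundary).
The algorithm is deterministic: identical inputs give identical modules.

## Perturbation scores

Differential expression uses a two-sample t-test on log2 values with an
empirical-Bayes variance squeeze: pooled per-gene variances $s_g^2$ (df
$d_g$) are shrunk to $\tilde s_g^2=(d_0 s_0^2+d_g s_g^2)/(d_0+d_g)$, where
$(d_0, s_0^2)$ come from moment-matching the log sample variances to a
scaled-F model (trigamma inversion; zero variances are offset to a tiny
fraction of the median first; an infinite $d_0$ — variances more concordant
than chi-square noise — collapses all genes to the common variance). The
moderated t has $d_0+d_g$ df, capped at the pooled residual df across genes:
the prior cannot carry more information than the data it was fitted to. The
implementation is closed-form and in-package; the test suite cross-checks it
against limma to 1e-8. Welch and plain pooled t-tests are available.

Gene scores are `-log10(p)`. The *absolute* pathway score of a set is the
mean of the three quartiles (Q1, Q2, Q3) of its DPG members' scores —
quartiles use linear interpolation (R type 7; the convention is a knob and
is recorded in outputs) — binned into levels 0–5 at 1.301, 2, 3, 4 and 6.
Bins are left-closed and right-open, and the 1.301 boundary is used
*literally* (the three-decimal print of `-log10(0.05)`), so p = 0.05 is the
largest p-value that leaves level 0.

The *relative* score measures whether a set's DPG members are more perturbed
than random genes: the observed statistic is the set's absolute score; the
null re-computes it on `n_perm = 10000` equal-size gene sets drawn without
replacement from all measured genes; the score is the fraction of
permutations the observed value strictly exceeds, binned at 0.5, 0.6, 0.7,
0.8, 0.9. The statistic, the null and the strict-greater counting are this
package's decisions (the source formulas are not published) and are flagged
in the run manifest. Under exchangeability the score is uniform on [0, 1]
up to permutation noise — verified at 1,000 null sets in the test suite.
When many sets are scored, sets with equal member counts share one
permutation null (the null depends only on the count), which keeps
ten-thousand-permutation runs at desk scale without changing any score's
distribution.

Pair-correlation summaries take per-pair Pearson correlation across all
samples and report the quartile mean of |r| per group (pairs bridging edges
above interaction-rate cutoffs 0.07/0.08/0.1/0.2, the excluded "other"
pairs, and per-module pairs). Tissue variance is the variance of per-tissue
*mean* expression (not of all samples — the per-tissue means are what the
variance maps colour), summarised per set by the quartile mean and binned
at 0.4, 0.5 and 0.7. A housekeeping gene must exceed the presence threshold
(matrix median by default) in *every* tissue and keep its between-tissue
variance under 0.5 log2² units; both knobs are explicit because no published
rule exists for the original list.

## What the synthetic data emulates — and what it does not

The generators reproduce the *statistical structure* the analysis relies
on, with one seed fanned out into per-stage substreams:

* `sim_genome()` packs gene bodies (1–3 kb) with ≥ 5 kb gaps onto equal
  8 Mb chromosomes and plants head-to-head pairs at controlled signed TSS
  distances. Defaults emulate the published table composition: 864 pairs
  among 17,280 genes (pairs ≈ 10% of genes), exactly 682 positive / 182
  negative. The ≥ 5 kb gap guarantees no unplanted pair, which is what makes
  recall = precision = 1 a meaningful check of the caller rather than of
  the generator.
* `sim_ontology()` builds layered random DAGs (each term takes 1–2 parents
  from the previous layer — acyclic with a unique root by construction).
  The per-namespace knob `q` is the *exact* probability that a planted
  pair's members share a non-root term: sharing is forced with probability
  `q`, disjointness otherwise. Defaults `q = 0.9 (CC), 0.6 (MF), 0.1 (BP)`
  encode the qualitative finding the method must recover: paired for
  compartment and function, divergent in process. The annotation density
  (95 terms per namespace, 2–4 direct annotations per gene) was fixed once,
  by a pilot, so that the chance overlap rate of *random* pairs (~0.09)
  sits just below `q = 0.1` — then BP-planted pairs are statistically
  indistinguishable from background, as they must be for the contrast to be
  a real null, while CC at 0.9 is far from it.
* `sim_expression()` writes `baseline + gene effect + group effect + noise`
  on the log2 scale. Differential sets shift in the case group only; DPG
  members of those sets can carry an extra shift (the DPG-specific signal
  the relative score must detect); `uniform_shift_sets` shift equally in
  *both* groups — expressed, but not differential. The recovery scenario
  used in tests surrounds these with a disease-like background (a few
  strongly perturbed sets, lfc 2, and a broad moderately perturbed response,
  lfc 0.7, ~30% of genes): against such a pool, sets whose only signal is a
  uniform shift score near relative level 0, while DPG-shifted sets reach
  levels 4–5. In a quiet, fully-null pool the uniform sets would be merely
  exchangeable (level ≤ 1 only ~60% of the time); it is the perturbed
  background that makes the relative score genuinely *relative*. Tissue
  mode plants housekeeping genes (elevated baseline, between-tissue wobble
  sd 0.1), tissue-specific genes (high in 1–2 tissues, low elsewhere), and
  moderately wandering remainder.

Not emulated: real chromosome lengths or promoter sequence features (CpG,
motifs, nucleosomes), annotation bias and term co-occurrence structure of
the real GO corpus, probe-level microarray noise and normalisation, and the
specific biology of the original tissues and diseases. Passing the recovery
suite therefore shows the *machinery* is correct and calibrated — not that
any particular biological conclusion transfers.

## Problem sizes and numerical details

The test and acceptance runs use sizes chosen to exercise every code path
at desk scale: similarity contrasts at 500 pairs vs 10,000 background over
50 seeded runs; pathway-score recovery on 2,000-gene matrices (10 vs 10
samples, noise sd 0.5) over 20 runs with 2,000 permutations (the acceptance
script's single run uses the full 10,000); null-uniformity at 1,000 null
sets and 10,000 permutations; oracle equivalence (Schlicker kernel,
rcmax.avg, KS statistic, hypergeometric tails, cohesiveness over all
subsets of 6-node graphs, quartile scores) at 1e-10.

Other conventions worth recording: p-values are floored at 1e-300 before
`-log10`; a gene with zero variance and zero difference gets t = 0, p = 1;
`sample_background()` redraws colliding pairs so both members are always
distinct; KS ties are handled by the ECDF definition (the brute-force
oracle in the tests evaluates the supremum over the pooled grid);
`filter_categories()` with equal-size sets falls back to name order.

## Limitations

The pairing rule reduces a many-to-many neighbourhood structure to a
matching; genes with several in-window partners contribute one pair, and a
different tie-break would move a handful of calls. One TSS per gene is
assumed — alternative promoters are out of scope. The greedy cohesiveness
search is a local optimiser; it recovers planted block structure exactly,
but on dense real networks different penalties or merge thresholds can
change module boundaries, which is why both are exposed. The relative-score
null treats genes as exchangeable units and ignores gene–gene correlation
within sets; correlated member scores widen the true null beyond the
permutation null, so relative levels on strongly co-expressed sets should
be read conservatively.
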
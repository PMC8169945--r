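# hspnet

Stratification of disease genes by the functional profiles of their
protein–protein interaction (PPI) subnetworks, built for the Hereditary
Spastic Paraplegias (HSPs) use case: a large panel of causative genes
("seeds"), heterogeneous clinical presentations, and the question of
whether clinical features map onto distinct molecular mechanisms.

The package is aimed at systems-biology analysts who have (a) a table of
evidence-annotated binary PPIs around a seed panel, (b) per-seed
clinical-feature codes, and (c) a GO-style annotation corpus with a
semantic dictionary — and who want a reproducible, fully tested path from
those inputs to clinically interpretable functional clusters.

## What it computes

1. **Evidence-scored network.** Each interaction scores
   `|publications| + |methods|`; duplicates merge by evidence union before
   scoring; edges with score < 3 (seen once, by one method) are removed.
2. **Core network.** Nodes touching ≥ 2 seeds are inter-interactome hubs
   (IIHs); the core is the induced subgraph on IIHs plus their adjacent
   seeds — the most interconnected part of the network.
3. **Three-tool enrichment with semantic merging.** Over-representation
   analysis under Fisher/Bonferroni, binomial/Bonferroni and
   hypergeometric/FDR configurations, with the enrichment ratio
   `ng / (ntg·nggo/ntag)`; terms map through a semantic dictionary into
   functional blocks; blocks confirmed by ≥ 2 of 3 tools keep the union of
   significant terms (`p_adjusted < 0.0166`, ≥ 4 genes).
4. **Keyword permutation enrichment.** Word-prefix keywords (`axo*`,
   `membrane*`, …) counted over enriched term names; null from 100,000
   without-replacement draws from the dictionary; upper normal-tail p.
5. **Stratification.** Per-clinical-feature subnetwork block profiles →
   PCA with coordinates scaled by explained variance → Euclidean
   hierarchical clustering → cluster count by silhouette (k = 2…6) and
   multiscale-bootstrap AU branch support → directional node-set overlaps
   with a Welch t-test of within- vs between-cluster overlap.

A synthetic-fixture generator (`fixture_config()`, `generate_fixture()`)
emulates all four inputs with a plantable two-cluster functional structure,
so every stage is testable offline.

## Worked example

```r
library(hspnet)

fx <- generate_fixture(fixture_config(rng_seed = 11))
config <- pipeline_config(ppi = fx$ppi, seeds = fx$seeds,
                          corpus = fx$corpus, dictionary = fx$dictionary,
                          n_boot = 200, n_sims = 2000, rng_seed = 11)
res <- run_pipeline(config)
res
#> <hsp_pipeline>
#>   global: 739 nodes / 878 edges; core: 218 nodes / 365 edges
#>   merged terms: 133; best k: 2; root-split AU: 1.00, 0.97
res$summary$seeds_retained
#> [1] "76/83, 91.6%"
res$summary$main_component
#> [1] "708/739, 95.8%"
tidy(res$stratification)
#> # A tibble: 6 × 2
#>   label cluster
#>   <chr>   <int>
#> 1 D           1
#> 2 E           1
#> 3 O           1
#> 4 P           1
#> 5 S           2
#> 6 T           2
```

Reading the numbers: of 1,018 raw interaction records, the score filter
leaves a global network of 739 proteins and 878 replicated interactions;
76 of the 83 seeds retain at least one interaction ("76/83, 91.6%") and
95.8% of nodes sit in one main connected component. The 218-node core
(hubs bridging ≥ 2 seed interactomes, plus those seeds) yields 133 merged
enriched terms. Stratifying the six clinical-feature subnetworks, the
silhouette prefers **two clusters** (mean width 0.97 at k = 2) and both
root-split branches carry AU support above 0.95 — the fixture's planted
{T, S} vs {E, P, O, D} functional dichotomy, recovered end to end.

Figures: `autoplot(res$stratification$embedding)` (scaled PCA),
`autoplot(res$stratification$au)` (dendrogram with AU values),
`plot_fold_change(res$fold_changes)` (per-cluster block fold changes vs
the core profile).

The methods vignette (`vignettes/network-stratification.Rmd`) documents
the model, every tunable parameter, the generator's assumptions and the
package's numerical conventions.

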
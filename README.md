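# synergynet

Reconstruction of phenotype-specific **gene-cooperation networks** from
log2 expression data, for analysts who want to find *pairs* of genes that
jointly discriminate a binary phenotype even when neither gene is a marker
on its own — the situation single-gene differential expression and
correlation-based coexpression both miss.

The core statistic is the **information synergy** of a gene pair
(G1, G2) with respect to a phenotype P:

```
Syn(G1, G2; P) = I(G1, G2; P) - I(G1; P) - I(G2; P)
```

where each `I(.; P)` is a plug-in mutual information between discretized
expression states and the phenotype, normalized by the phenotype entropy
H(P) so that every term lies in [0, 1] and the synergy score in [-1, 1].
Positive synergy means cooperation, negative synergy redundancy.
Significance comes from a phenotype-permutation test (the same B
permutations reused across pairs; one-sided empirical p with +1 smoothing)
followed by Benjamini–Hochberg adjustment across all pairs; significant
positive pairs form the edges of an undirected network. On top of the
network the package provides:

* **gene selection** by metabolite-trend matching across three treatment
  conditions (BSA control / palmitate / oleate) plus pairwise Welch
  t-tests;
* **joint-pattern classification** of cooperative pairs into gap /
  substitute / on-off configurations;
* **topology diagnostics** against a size-matched Erdős–Rényi graph
  (degree histograms, KS statistic);
* **pathway enrichment** (hypergeometric tail, BH across pathways) and
  **pathway–neighbor association** ranking (hypergeometric tail on a
  neighbor's pathway adjacency given its degree, BH per pathway);
* a **differential-correlation baseline** network (Fisher z test on
  within-class correlations) for head-to-head comparison;
* a **synthetic-data generator** with planted cooperative pairs, trends,
  pathways and hub neighbors, so every stage is testable without external
  data.

Everything is tidyverse-flavored: analysis results are tibbles, fitted
objects have `tidy()` / `glance()` methods and `autoplot()` /
`plot_pair()` figures, and all file formats are plain text (expression and
metadata TSV, GMT gene sets, SIF edge lists, JSON run manifest).

## Worked example

Simulate a dataset with one planted pathway — five member genes plus a hub
gene whose pairing with every member follows the gap pattern — and run the
full pipeline:

```r
library(synergynet)

trends <- setNames(rep(c("I", "II", "III", "IV"), 3), sprintf("g%03d", 7:18))
cfg <- sim_config(n_genes = 18,
                  pathways = list(list(name = "PW", n_members = 5, hub = TRUE)),
                  pathway_delta = 3, trends = trends, seed = 2)
ds <- simulate_dataset(cfg)
pl <- run_pipeline(ds, gene_sets = attr(ds, "gene_sets"), B = 1000, seed = 9)
pl
#> <synergy_pipeline>
#>   selected genes : 18 / 18
#>   pairs tested   : 153 (B = 1000)
#>   synergy network: 6 genes, 5 edges
#>   pathways       : 1 significant / 1 tested
#>   top neighbor   : g006 (pathway PW, p_adj = 0.167)
#>   diffcorr net   : 6 genes, 15 edges
```

All 18 genes survive trend and differential-expression selection (the planted genes
through their intrinsic palmitate shift, the background genes through
their assigned trends); of the 153 candidate pairs, exactly the five
hub–member pairs are significant, so the network is the hub `g006` plus
the five pathway members. The pathway is enriched and the hub is its
top-ranked neighbor:

```r
pl$enrichment
#>   pathway n_background n_network        p    p_adj significant
#> 1 PW                 5         5 0.000700 0.000700 TRUE

pl$associations
#>   pathway gene      x     N     n     k     p p_adj  rank significant
#> 1 PW      g006      5     6     5     5 0.167 0.167     1 FALSE
```

Read the association row as: neighbor `g006` touches `x = 5` of the
`n = 5` pathway genes present in the `N = 6`-gene network, using `k = 5`
of its edges; `p = 0.167` is the hypergeometric tail — the floor value in
a network this small, which is why the hub ranks first while the
`significant` flag stays off (tiny-network p-values are bounded below).
The same pipeline on a 570-gene network yields tails in the 1e-3 range for
a neighbor with x = 3, n = 15, k = 12.

The differential-correlation baseline finds the planted pairs' *class
correlations* unchanged (the gap pattern shifts the joint mean, not the
within-class correlation), illustrating the contrast the synergy statistic
exists for.

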
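---
title: "Reconstructing gene-cooperation networks from information synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-cooperation networks from information synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergynet)
library(dplyr)
```

## The model

Two genes *cooperate* with respect to a binary phenotype when their joint
expression tells you more about the phenotype than the two genes do
separately. synergynet quantifies this with the information synergy of a
pair $(G_1, G_2)$ and phenotype $P$:

$$\mathrm{Syn}(G_1, G_2; P) \;=\; I(G_1, G_2;P) \;-\; I(G_1;P) \;-\; I(G_2;P),$$

where each $I(\cdot\,;P)$ is a mutual information between discretized
expression states and the phenotype, estimated by the plug-in formula and
divided by the phenotype entropy $H(P)$. For a binary phenotype this
normalization makes every term lie in $[0, 1]$ and the synergy score in
$[-1, 1]$: positive scores mean cooperation (the joint distribution
separates the classes better than the marginals combined), negative scores
mean redundancy (both genes carry the same information), and scores near
zero mean the pair is jointly uninformative. Pairs whose synergy is
significantly positive become the edges of an undirected
*gene-cooperation network*; everything downstream — degree structure,
pathway enrichment, neighbor association — is read off that network.

The intended study design behind the defaults is a three-condition
hepatocyte experiment (BSA control, palmitate, oleate) in which palmitate
induces a toxic phenotype, so toxic samples coincide with the palmitate
condition. Nothing in the code depends on that identification: conditions
and phenotype labels are independent columns of the sample table.

## Mutual-information estimation

Expression is continuous, so mutual information requires a discretization.
Each gene is discretized on its own into at most `n_states` (default 3)
bins by the exact minimum within-cluster-variance partition (1-D k-means
solved by dynamic programming over the sorted unique values — deterministic,
tie-safe, order-invariant). For the joint term two schemes are available:

* **grid** (default): the joint state of a sample is the pair of its two
  marginal bins, at most `n_states^2` states. Because this partition
  *refines* both marginal partitions, the plug-in estimate satisfies
  $\hat I_{12} \ge \max(\hat I_1, \hat I_2)$ on every dataset. Two
  consequences follow by construction rather than by post-hoc clamping:
  the synergy score always lies in $[-1, 1]$, and a duplicated gene
  (or any pair carrying identical information) can never score positive
  synergy. The scheme is fully deterministic.
* **cluster**: k-means on the standardized pair with `n_states^2` centers
  (10 restarts, seeded). It adapts to oblique structure (a diagonal "gap"
  is captured by clusters aligned with the gap), at the price of losing the
  refinement guarantee: with 9 free clusters versus 3 marginal bins the
  plug-in bias of the joint term exceeds that of the marginals, and weakly
  informative duplicated genes can drift to small positive synergy.

We made grid the default because the redundancy sign and the $[-1,1]$
bounds are structural properties of the statistic, not empirical ones, and
an estimator that guarantees them is easier to reason about; the
permutation test absorbs the power difference between the two schemes in
the regimes we simulate. Both schemes are exposed and tested.

Estimation bias is real at these sample sizes: with $n = 60$ samples,
9 joint states and 2 classes, the expected plug-in excess of the joint term
over the marginal terms under independence is roughly
$(9-1-2\cdot 2)(2\,n\ln 2)^{-1} \approx 0.05$ on the normalized scale, so
raw synergy scores of null pairs sit slightly above zero. This is why
significance is never read off the score itself but always from the
permutation test, which carries the same bias in its null draws.

## Significance: permutation test and BH

Phenotype labels are permuted `B` times (default 1000); the same `B`
permutations are reused for every pair so that scores are comparable across
pairs within a run. The one-sided empirical p-value for positive synergy is
$(1 + \#\{b: \mathrm{syn}_b \ge \mathrm{syn}_{obs}\})/(B+1)$, with ties
counted against significance. Benjamini–Hochberg is applied once across all
tested pairs, and edges are pairs with positive synergy and adjusted
p below `edge_alpha` (default 0.05).

One arithmetic consequence deserves emphasis. The smallest achievable
p-value is $1/(B+1)$, so in a scan of $m$ pairs of which $t$ reach that
floor, the smallest achievable BH-adjusted value is $m /((B+1)\,t)$. No
pair can be declared significant at level $\alpha$ unless

$$\frac{t}{m} \;>\; \frac{1}{(B+1)\,\alpha}.$$

A 610-gene scan ($m = 185{,}745$) with $B = 1000$ and 4376 floor-level
pairs clears this bound ($0.0424 < 0.05$) — narrowly. A 50-gene benchmark
($m = 1225$) with 5 planted pairs and $B = 200$ cannot: its best adjusted
value is $1.22$. Small benchmarks must therefore either use a denser
fraction of true pairs or raise `B`; the package's recovery tests use
all-planted 10-gene fixtures at $B = 200$ (best adjusted value
$45/(201\cdot 5) = 0.045$) and report the granularity bound here so users
scaling down do not mistake it for a power failure.

## Gene selection

Before scanning, the gene universe is reduced the way the assay design
suggests: expression is log2 scale (with probe-to-gene averaging in
`preprocess()`), each gene's per-condition means are matched against four
metabolite trends — strict orderings over (BSA, palmitate, oleate):
I `BSA < PA > OA`, II `BSA > PA < OA`, III `BSA < PA < OA`,
IV `BSA > PA > OA` — and genes failing every trend, or not differentially
expressed in any pairwise Welch two-sample t-test at `select_alpha`
(default 0.05), are dropped. Welch rather than pooled-variance is used
because group variances in expression data are rarely equal; means rather
than medians summarize conditions; ties match no trend, and an optional
tolerance band (`trend_tol`, default 0) makes near-ties explicit. All of
these are choices the underlying method leaves open; each is exposed as an
argument.

## Joint-expression patterns

Positive-synergy pairs are classified into the three canonical
configurations: **gap** (genes positively correlated, phenotype separated
along the difference axis), **substitute** (negatively correlated,
separated along the sum axis), and **on/off** (jointly silent in one class,
jointly active in the other). The rule compares Welch t statistics of the
phenotype along the rotated axes $(G_1 \mp G_2)/\sqrt2$ and requires the
winning axis to actually separate the classes (t-test p < 0.05); otherwise
the pair is called on/off. Without that significance gate a pattern with no
linear separation at all — exactly the on/off geometry — would be assigned
gap or substitute by the sign of noise.

## Pathway statistics

Enrichment: for a pathway with $n$ genes among $N$ background genes, of
which $x$ fall in the $k$ network genes, the one-sided hypergeometric tail
$\sum_{i \ge x} \binom{n}{i}\binom{N-n}{k-i}/\binom{N}{k}$ is computed via
`stats::phyper` (log-space stable), BH-adjusted across pathways. The
background defaults to the selected-gene universe, because that is the
population from which network genes were drawn; the full pre-selection
universe can be substituted.

Association: for each enriched pathway, the non-member network genes
adjacent to at least `min_connections` (default 3) pathway genes are scored
by the same tail with $N$ the network size, $n$ the pathway genes in the
network, $k$ the neighbor's degree and $x$ its pathway adjacency; BH is
applied per pathway across its tested neighbors. Rows are ordered by
adjusted then raw p then gene id, but the `rank` column uses min-rank so
neighbors with identical $(x, N, n, k)$ — hence identical p — share a rank;
with small integer counts exact ties are common and breaking them
alphabetically would be arbitrary.

## Differential-correlation baseline

The comparison method tests, for every pair, whether the within-class
correlation differs between phenotypes: Fisher z-transform each class
correlation and compare
$z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ against a standard normal,
two-sided, BH across pairs. Pearson correlation is the default with
Spearman exposed. The two methods are sensitive to different structure:
a gap pair shifts the joint mean between classes while leaving each class's
correlation untouched, so it is invisible to differential correlation but
conspicuous to synergy; the package's head-to-head tests verify exactly
this contrast on generator output.

## The synthetic-data generator

`simulate_dataset()` produces log2-scale expression with known ground
truth; it emulates the statistical structure the analysis assumes, not the
measurement process. With `s = +1` for toxic and `-1` for nontoxic samples,
shared latent `C ~ N(0, sigma_c2)` and noise `e ~ N(0, noise_sd^2)`:

* **gap** pairs: `G1 = C + s d/2 + e`, `G2 = C - s d/2 + e`;
* **substitute** pairs: `G1 = C + s d/2 + e`, `G2 = -C + s d/2 + e`;
* **on/off** pairs: nontoxic samples near the joint origin
  (`N(0, 0.1 I)`), toxic samples uniform on an annulus of radius 2–3;
* **redundant** genes: a lone mean shift between classes;
* **pathway hubs**: a hub gene and `n_members` member genes all sharing one
  latent `C`, every hub–member pairing a gap pair — the hub becomes a
  cooperative neighbor of the whole pathway in the reconstructed network;
* **trends**: additive per-condition offsets realizing a trend code, scaled
  by `trend_effect`;
* everything else: i.i.d. noise.

Defaults are fixed once: 30 toxic + 30 nontoxic samples (toxic = palmitate;
nontoxic split evenly between BSA and oleate — per-condition sample counts
are not published for this design, so tens of samples per class is the
realistic desk scale), `noise_sd = 0.3` log2 units, planted effect
`delta = 2`, latent variance `sigma_c2 = 4`. The latent variance default
follows from the pattern's defining property: for the marginals to stay
weak while the difference axis separates the classes, `sigma_c2` must
dominate `(delta/2)^2` (at `sigma_c2 = delta^2` the per-gene class shift is
half a marginal standard deviation, while the difference axis separates by
almost five of its standard deviations). At `sigma_c2 = 1` the same pairs
are still cooperative but each gene is individually a strong marker, and
estimated synergy can touch zero in a minority of runs — the tests cover
both regimes.

All randomness flows from one root seed through fixed per-role substreams,
so a configuration is bit-reproducible and insensitive to which other roles
are present. `simulate_hub_network()` complements this with a network-level
testbed for association ranking: a sparse Erdős–Rényi background
(`edge_prob = 0.04`, mean degree ≈ 2.4 at 60 genes) with a planted
low-degree hub adjacent to 3 pathway genes. The sparsity reproduces the regime of real cooperation networks, where
most of a pathway's neighbors touch only one or two of its genes and the
top-ranked neighbor has minimal degree among those tested; in a dense
background, chance neighbors
with overlap 4–5 would legitimately outrank any planted hub.

What the generator does **not** emulate: probe-level microarray artifacts,
normalization and dye effects, heavy-tailed or correlated noise,
batch structure, and metabolite flux values themselves (only the trend
codes). Passing tests on this generator therefore demonstrate correctness
of the statistics and the machinery, and the qualitative contrasts between
methods — not performance on real arrays.

## Numerical and degenerate-input choices

* Constant genes: a single expression state; mutual information 0; Welch
  tests on constant groups return p = 1 rather than erroring inside scans.
* A single-phenotype dataset is an error everywhere (`degenerate
  phenotype`), as is a class with fewer than 4 samples in the
  differential-correlation test (the Fisher variance term needs `n > 3`).
* Permutation p-values use +1 smoothing, so p = 0 never occurs and BH input
  is always valid.
* `mutual_information` clamps tiny negative rounding residue (~1e-16) of
  the plug-in sum at zero; this is floating-point hygiene, not score
  clamping.
* Problem sizes in the test suite are scaled for a single CPU: scans of
  10–50 genes, B = 10–1000, 5–20 seeds per property; the full suite runs
  in about a minute.

## Known limitations

* The clustering-based estimator this statistic is usually paired with is
  not fully specified in the literature, so the two schemes here are
  principled concretizations, and absolute synergy values
  are estimator-dependent (significance calls are far less so).
* Permutation granularity bounds small-scan sensitivity, as derived above.
* This package excludes negative-synergy edges from the network, taking the cooperation framing
  literally (a redundant pair is not a cooperating pair).
* BH is applied once across all scanned pairs; if the pair universe is
  itself selected post hoc, the FDR guarantee refers to the scanned
  universe only.

## A minimal run

```{r example, eval = FALSE}
trends <- setNames(rep(c("I", "II", "III", "IV"), 3), sprintf("g%03d", 7:18))
cfg <- sim_config(n_genes = 18,
                  pathways = list(list(name = "PW", n_members = 5, hub = TRUE)),
                  pathway_delta = 3, trends = trends, seed = 2)
ds <- simulate_dataset(cfg)
pl <- run_pipeline(ds, gene_sets = attr(ds, "gene_sets"),
                   B = 1000, seed = 9)
pl
pl$enrichment
pl$associations
```
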
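---
title: "Pathway cross-talk inhibition networks: model and design notes"
author: "pciNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway cross-talk inhibition networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pciNet)
```

# The model

`pciNet` treats a tumour subtype as a *network of cross-talking pathways*
rather than a list of de-regulated genes. The pipeline has three layers.

**Layer 1 — which pathways are involved.** Per case-vs-control comparison,
genes are tested with a per-gene Welch (unequal-variance) two-sample test on
log2(CPM + 1). The log2 fold change is the difference of mean log-scale
values, so it is a median-style ratio estimate robust to a few extreme
counts. DEGs must pass |log2FC| > 1 *and* BH-adjusted p < 0.01, both strict
inequalities. The DEG list is then mapped onto a pathway collection with
one-sided Fisher exact tests (over-representation), BH-corrected across the
pathways of that run, again at strict adjusted p < 0.01. The gene universe
is the set of genes measured in the dataset, and every pathway is
intersected with that universe once at load time; pathways with fewer than
two measured genes are dropped because their within-sample standard
deviation (needed below) is undefined.

**Layer 2 — how strongly pathway pairs cross-talk, per sample.** For a
sample and a pathway *x* with measured genes *g*, let M~x~ and S~x~ be the
mean and the sample (n−1) standard deviation of that sample's expression
over *g*. The discriminating score of an ordered pair is

$$\mathrm{DS} = \frac{M_x - M_y}{S_x + S_y}.$$

DS is antisymmetric and invariant to an additive shift applied to the whole
sample (both means shift equally), so it captures *relative* activity of two
pathways, not overall expression level. Each sample yields one DS value per
unordered pathway pair (canonical lexicographic order), giving a
samples × P(P−1)/2 feature matrix.

**Layer 3 — which pairs discriminate, and what a drug could break.** Every
pair feature is scored by a random forest under stratified k-fold
cross-validation, and the top-k pairs per bootstrap are kept if their AUC on
a held-out split reaches a floor. Bootstraps are class-balanced 60/40
Monte Carlo splits. The retained pairs, aggregated across bootstraps, form
an undirected pathway network. Its global efficiency is

$$\mathrm{NE} = \frac{\sum_{i \neq j} 1/d(i,j)}{N(N-1)},$$

with unit edge lengths and 1/∞ = 0 for disconnected pairs, so NE ∈ [0, 1]
with NE = 1 exactly for the complete graph. Inhibiting a pathway set *k*
deletes those nodes and their incident edges; the efficiency of the reduced
network, nNE, is normalized by the *reduced* node count. The inhibition
strength is

$$\mathrm{PCI} = 100 \times \left(1 - \frac{\mathrm{nNE}}{\mathrm{NE}}\right),$$

the percentage of network activity abolished; it is negative when deleting
the node *raised* efficiency. The DTPN (drug target pathway network) is the
subnetwork of nodes whose single deletion gives nNE < NE strictly; drugs
attach to DTPN pathways by Fisher enrichment of their target genes, and all
2^m − 1 subsets of a drug's m pathways are scored by PCI to expose
synergistic combinations.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lfcThreshold` | 1 (log2 units) | strict DEG fold-change cut |
| `pThreshold` | 0.01 | strict adjusted-p cut (DEA and enrichment) |
| `pseudocount` | 1 | added before log2; keeps zero counts finite |
| `trainFraction` | 0.6 | Monte Carlo training share |
| `nBootstraps` | 50 | Monte Carlo repetitions |
| `topK` | 10 | pairs kept per bootstrap |
| `cvFolds` | 10 | stratified CV folds for the AUC |
| `nTrees` | 500 | forest size; mtry = √(feature count) = 1 per pair |
| `testAUCFloor` | 0.5 | held-out AUC a pair must reach to be "validated" |
| `minFrequency` | 1 | bootstrap selection count an edge needs |
| `cap` (DS) | 1e6 | magnitude used when S~x~ + S~y~ = 0 with unequal means |
| `maxSubset` | 6 | drug-combination enumeration cap (≤ 63 subsets) |

# Design choices where the design was open

* **"p < 0.01" is read as the BH-adjusted p**, both in DEA and enrichment,
  because the correction is part of both stages; the raw-p reading is
  available via `deaConfig(useAdjusted = FALSE)`.
* **DS operates on log2(CPM + 1)**. The score's denominator is a raw
  standard deviation, so on a linear counts scale a single highly expressed
  gene would dominate every pathway mean; the log scale keeps DS driven by
  broad pathway activity. The scale is explicit metadata on the dataset and
  is never guessed.
* **Per-pair AUC is univariate**: each pair's DS feature is scored by its
  own forest. This is the only reading that yields a per-pair AUC directly;
  scoring by variable importance from one joint forest would rank pairs on
  a different, non-AUC scale.
* **The cross-validated AUC pools out-of-fold probabilities.** All
  out-of-fold predicted probabilities are ranked once against the true
  labels (the cvAUC-style pooled estimator). With k = 10 and balanced
  classes a single fold holds only a few samples per class, so per-fold
  AUCs are coarse (granularity 1/(n₁n₂) per fold) and averaging them has
  markedly higher null variance than pooling; pooling also keeps the
  constant-feature case at exactly 0.5 under the average-rank tie
  convention.
* **Class balancing is downsampling without replacement** to the minority
  class size, per bootstrap. Oversampling would let duplicated samples
  straddle the train/test boundary and leak.
* **Inhibition is node deletion with renormalization by the reduced N**,
  not mere edge removal. Edge removal with fixed N makes NE monotonically
  non-increasing, which cannot produce the empirically important case of an
  inhibition that *raises* efficiency (deleting a peripheral node of a hub
  topology does). The edge-isolation variant is kept as
  `inhibit(..., mode = "isolate")` for sensitivity analysis.
* **Network construction uses the union of validated pairs**
  (`minFrequency = 1`). How the per-bootstrap selections are merged into
  one network is genuinely open; the union is the most inclusive choice and
  a minimum-frequency filter is exposed for stricter consensus networks.
* **Edge weights (selection frequencies) are metadata only**; no weighting
  rule for path lengths is defined, so all shortest paths use unit lengths.
* **Ties** in pair ranking are broken by the canonical pair name, making
  runs reproducible; all randomness flows from one master seed through
  per-bootstrap derived seeds.

# What the synthetic generator emulates — and what it does not

`simulationConfig()` describes a two-class study with planted truth. Counts
are log-normal: per-gene baseline log2 means ~ N(5, 2), per-observation
Gaussian log2 noise (sd 0.5), exponentiated to positive pseudo-counts.
Case samples get a per-pathway log2 effect added to the genes of each
perturbed pathway. The defaults are 30 case vs 30 control samples and a
55-pathway collection (20 genes each, disjoint, plus 100 background genes)
whose first five pathways are perturbed with effects 1.5, 1.8, 2.1, 2.4,
2.7. The effects are deliberately *distinct*: DS cancels a shift common to
both pathways of a pair, so equal effects would plant DEGs but no
cross-talk signal. A 13-drug panel draws each drug's targets from one
pathway (80% of its genes).

The generator does **not** emulate negative-binomial overdispersion,
batch effects, library-size artifacts, correlated gene-gene noise within
pathways, or realistic pathway-size distributions. Passing recovery tests
therefore demonstrates that the pipeline's machinery is sound — DEGs found,
enrichment scoped, DS signal propagated, pairs ranked, networks probed —
not that the method's biological findings on real tumour data are
reproduced. Real count data should additionally be checked with a
dispersion-aware DE method; the DE stage is pluggable behind
`differentialExpression()` for that reason.

# Numerical conventions and degenerate inputs

* Welch test with zero pooled variance: p = 1 when the group means agree,
  p = 0 otherwise (the identical-groups case is what occurs in practice).
* DS with S~x~ + S~y~ = 0: 0 for equal means, ±`cap` otherwise, keeping the
  classifier's feature matrix finite.
* NE of a graph with N ≤ 1 is defined as 0; disconnected pairs contribute 0.
* PCI is undefined (error) when NE = 0.
* An empty enrichment query returns p = 1 with a warning; a bootstrap with
  fewer than two enriched pathways is recorded as empty, not fatal.
* Rounding: PCI is computed and stored at full precision; display rounding
  (two decimals, or one where a table prints one) is applied only at
  reporting time.

# Problem sizes used by the test-suite

The suite exercises the full pipeline at reduced but non-trivial sizes
chosen so every stage runs in seconds: recovery runs use the default
30 + 30 samples and 55 pathways with 10 bootstraps and 100-tree forests
(the AUC of a univariate forest stabilises well below 500 trees at these
sample sizes); pipeline integration runs use 20 pathways, 3 bootstraps and
60-tree forests. Graph oracles are exhaustive on networks of up to 12
nodes, where Floyd–Warshall recomputation is instant.

# Known limitations

* The DE stage is a Welch test, not a count-model (edgeR/DESeq2-style)
  fit; with very small groups or strong overdispersion its p-values are
  approximate.
* Fisher enrichment ignores gene-gene correlation, as usual for
  over-representation tests.
* PCI treats all edges as identical; there is no dose–response notion of
  partial inhibition, and no weighting of cross-talks by strength.
* Enumerating drug subsets is exponential; the default cap of 6 associated
  pathways (63 subsets) reflects that published drug–pathway tables rarely
  exceed four.
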
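---
title: "Fuzzy mining of cis-regulatory modules: model, parameters and design notes"
author: "fuzzycrm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy mining of cis-regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzycrm)
```

## The problem and the model

Transcription of a gene is rarely controlled by one transcription factor
(TF) alone. Functionally related TFs bind in *cis-regulatory modules*
(CRMs): groups of binding sites packed into a few hundred base pairs.
Given only a genome-wide list of TF binding sites (TFBSs) — experimentally
mapped or scanner-predicted — the task is to find TF combinations that
co-occur in such tight neighbourhoods far more often than chance allows.

`fuzzycrm` models this in four stages.

**1. Clustering.** Site anchor positions (interval midpoints by default)
are clustered per chromosome by agglomerative average linkage; merging
stops once the closest pair of clusters is further apart than
`cluster_threshold` (300 bp by default — the length scale of a typical
CRM). In one dimension the average pairwise distance between two
contiguous clusters equals the difference of their means, so the
implementation merges adjacent clusters by mean difference. That identity
also guarantees clusters stay contiguous, so no generality is lost.

**2. Fuzzy transactions.** A CRM has no sharp edge, and a hard window
would make a site 1 bp outside it count for nothing. Each cluster is
therefore converted to a *fuzzy transaction*: membership of a site falls
from 1 (within `a` bp of the cluster centroid `c`, the median anchor) to 0
(beyond `a + b` bp) along a linear ramp — a trapezoidal membership
function. A TF bound at several sites of one cluster takes the maximum
degree, which preserves the best single site and keeps degrees in
`[0, 1]`; every positive-degree site is retained in the transaction's site
pool for stage 4.

**3. Mining and significance.** Frequent TF combinations are extracted
with a fuzzy frequent-pattern-tree (FP-tree): transactions sharing their
leading frequent items share tree paths, and each node stores, sparsely,
the membership degrees of the transactions routed through it. Itemset
degree in a transaction is the *minimum* of the member degrees (the
minimum t-norm — the standard fuzzy intersection, and the choice that
makes support anti-monotone, so subset pruning stays valid); support is
the sigma-count of those minima divided by the transaction count `N`.
During traversal the per-node degree vectors are min-combined into
*copies*, never mutated, so processing an upper level cannot corrupt a
lower one and mining the same tree twice gives identical results. Every
reported combination is scored against an independence null: the
probability that TFs with marginal supports `p_i` (taken from the same
database) co-occur at least `k = ceil(N * supp)` times if they bound
independently, i.e. the upper binomial tail at `p0 = prod(p_i)`. The tail
is evaluated through the regularised incomplete beta (`pbinom`), which is
numerically equivalent to exact summation — the test suite checks
agreement to below 1e-10 across the full count grid up to `N = 50`.

**4. Overlap resolution.** Scanner-predicted sites frequently overlap; a
combination may be counted in a transaction even though its sites could
never be bound simultaneously. Instead of discarding overlapping pairs,
each reported itemset is refitted into each transaction: choose one site
per TF, pairwise disjoint (half-open intervals; abutting sites are
compatible), maximising the minimum degree. The optimum is found exactly
by depth-first enumeration with a branch-and-bound on the running minimum
— itemsets hold 2–4 TFs and clusters hold few alternative sites per TF, so
the search space is tiny. Each successful fit is a concrete CRM instance;
the refitted supports define `postfit_support <= support`.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `cluster_threshold` | 300 | bp | average-linkage stop distance; sets the locus scale |
| `core_halfwidth` (`a`) | 150 | bp | flat degree-1 core of the trapezoid |
| `ramp_width` (`b`) | 100 | bp | width of each fuzzy border |
| `crisp_halfwidth` (`W`) | `a + b` = 250 | bp | hard border of the crisp baseline |
| `min_support` | 0.01 | — | minimum fuzzy support |
| `max_pvalue` | 0.01 | — | significance threshold (raw p by default) |
| `min_size` | 2 | TFs | single TFs are not modules |
| `count_rounding` | `ceil` | — | discretisation of the fuzzy count |
| `site_anchor` | midpoint | — | the point of a site that is clustered |

The trapezoid defaults make the degree-1 core match the clustering scale
(sites within 150 bp of the centroid count fully) and let influence decay
to zero by 250 bp — consistent with CRMs being "a few hundred bp" long.
The crisp default `W = a + b` makes the hard window coincide with the
trapezoid's support, which is the fair baseline: any difference between
modes is then due to border softness, not window size. `ceil` is the
conservative count discretisation — it starts the binomial tail at the
smallest integer count consistent with the observed sigma-count, never
earlier, so significance is not inflated by rounding; `floor` and `round`
are available for sensitivity analysis. Raw p-values are reported by
default; `bh = TRUE` switches the threshold to Benjamini–Hochberg-adjusted
values when a controlled false discovery rate across the reported list
matters more than per-itemset calibration.

## Numerical and tie-break conventions

Fixed, documented choices keep runs bit-reproducible across platforms:

* Merging is allowed at distance exactly `cluster_threshold` (inclusive).
* Among equal-distance merge candidates the leftmost pair wins.
* Header-table order is descending support with lexicographic tie-break;
  output itemsets are sorted by significance, then support, then label.
* Centroids use `stats::median`: the mean of the two middle anchors for
  even-sized clusters.
* Refit ties are broken by higher total degree, then leftmost locus.
* Clusters whose every site gets degree 0 (possible only when `a + b` is
  small relative to the cluster spread) are dropped from `N` but counted
  in the `n_empty` diagnostic.
* Degrees are serialised at 4 decimals — ample for degrees that move in
  steps of `1/(2b)` per base pair at the default ramp width.
* Empty inputs are legal everywhere and produce empty outputs, not errors.

A database re-read from a transaction file carries TF–degree pairs but no
site-level provenance, so it supports mining and scoring; the overlap
refit, which needs the underlying intervals, refuses it with an
explanatory error rather than inventing coordinates.

## What the synthetic generator emulates — and what it does not

`simulate_tfbs()` produces a background of uniformly placed,
uniformly labelled sites per chromosome (label frequencies can be skewed
via `tf_freqs`) plus planted modules: loci at which a chosen TF subset
co-occurs within a small window, sites kept disjoint by rejection
sampling (capped at 1000 attempts, then an explicit error). This captures
exactly the two regimes the method must separate — independent background
co-occurrence versus genuine modular co-binding — with known ground truth.

It does **not** emulate: sequence composition or scanner score
distributions, clustered/regulatory-region-biased background placement,
chromatin accessibility, strand effects, or correlated non-module TFs.
Passing the recovery tests therefore demonstrates that the statistical
machinery detects planted co-occurrence against independent noise at
realistic densities; it does not certify performance on any particular
real genome or site predictor.

The validation experiments use one fixed regime, chosen to be realistic
for a small eukaryotic genome and kept modest so the whole suite runs in
about a minute: ten 200 kb chromosomes, a 12-TF alphabet, 2000 background
sites of 10 bp (about one site per kb, giving ≈1500 clusters at the 300 bp
threshold), and — in the planted condition — one module of three TFs at 50
loci within 150 bp windows, i.e. planted support ≈ 0.03 against a
three-way independence expectation of ≈ 1e-3. Recovery is measured over
20 seeds; the pure-noise condition is the same landscape without planted
modules, the in-silico analogue of re-running the pipeline on randomised
genomes, and is expected to report (near) zero combinations. The
oracle-equivalence experiments use 200 random databases of up to 12 items
and 200 transactions with uniform degrees and random support thresholds;
the Monte-Carlo check of the binomial tail uses 100 000 replicates at
`N = 20`.

## Design decisions on genuinely open points

* **Anchor point.** Sites are clustered by their midpoints: the midpoint
  is the only anchor invariant under strand flips and site-length
  differences. `site_anchor = "start"` is available for exact replication
  of position-list analyses.
* **Self-calibrated null.** The null marginals are the single-item
  supports of the analysed database itself. This keeps the null faithful
  to the observed per-TF site densities, at the cost of a slight
  conservatism for items that are themselves part of strong modules.
* **Both supports are reported.** Whether thresholds should apply before
  or after overlap resolution is ambiguous; itemsets falling below
  `min_support` after refitting are flagged (`postfit_dropped`) rather
  than removed, and p-values are not recomputed post fit.
* **Zero-degree items are dropped** from transactions, and transactions
  that lose all items are excluded from `N`: an empty cluster carries no
  item-frequency information for the null.
* **Model-object interface.** The pipeline is exposed as one fitting-style
  entry point, `crm_mine()`, returning a classed object with `print`,
  `summary`, `coef` (null marginals), `plot` and `simulate` (null
  databases) methods — `predict` and `residuals` have no meaning for an
  itemset miner and are deliberately absent.

## Limitations

* The independence null ignores spatial structure within clusters and
  correlations induced by shared sequence preferences; p-values are
  calibrated per itemset, not across the exponentially large hypothesis
  space (use `bh = TRUE` for list-level control).
* Average-linkage clustering with a global threshold cannot adapt to
  locally varying site density.
* The refit maximises the minimum degree only; among degree-ties it
  prefers total degree, which may not be the biologically preferred
  arrangement.
* Runtime of the miner grows with the number of frequent itemsets, which
  explodes at very low support thresholds on dense databases; the
  brute-force enumerator is capped at 20 items by design.

## A minimal session

```{r example, eval = FALSE}
cfg <- synthetic_config(
  planted_modules = list(list(tfs = c("TFA", "TFB", "TFC"),
                              n_loci = 50, window = 150)),
  seed = 7)
sim <- simulate_tfbs(cfg)
fit <- crm_mine(sim$sites)
summary(fit)
head(coef(fit))
```
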
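---
title: "Methods: time-course ranking, enrichment and information clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course ranking, enrichment and information clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressrank)
```

## The analysis problem

`stressrank` implements the analysis of a short expression time course
with one untreated control group and several post-treatment time points —
the motivating design is acute restraint stress in mouse hippocampus,
profiled 3, 12 and 24 hours after a single stressor, with 9 animals per
group (27 stressed, 9 control). The question is not "which genes differ at
time t" but "which genes moved strongly at *any* point of the course, in
either direction", followed by a systems-level summary: which gene sets
are enriched among the movers, and how do the significant sets relate to
one another.

## Log2 ratio trajectories

Intensities are strictly positive array signals. For gene $g$ the control
reference is the median intensity over the control biological replicates.
Each treatment replicate gives a log2 ratio against that reference, and
the trajectory value at time point $t$ is the replicate median:

$$ r_{g,t} = \mathrm{median}_j \; \log_2 \frac{x_{g,t,j}}{\mathrm{median}_i \, x_{g,\mathrm{ctrl},i}} . $$

Medians at both levels make the construction robust to a single aberrant
replicate. Per-animal pairing is impossible with unpaired controls, so a
common per-gene reference is the natural choice. Genes with any missing
intensity are dropped (with a message) before ratios are computed, so all
downstream values are finite.

When each array is itself a pool of several animals, `pool_replicates()`
averages `pool_size` consecutive subjects (default 3) on the intensity
scale into one biological replicate. The default design — 9 subjects per
group pooled 3-to-1 into 3 replicates — keeps both readings of "9 mice,
3 biological replicates" reachable: set `pool_size = 1` for 9 independent
replicates per group.

## Sum-squared ranking and the heatmap matrix

The per-gene importance score is the sum of squared log2 ratios across
the course,

$$ S_g = \sum_t r_{g,t}^2 , $$

large when the gene is strongly regulated at any time point in either
direction, and invariant to the sign of each excursion. Genes are sorted
by $S$ descending; ties (rare with continuous data, common in degenerate
fixtures) break lexicographically by gene id so the ranking is fully
deterministic. The top 75 genes (`top_k`, the study's plotted count) form
the heatmap matrix, with values symmetrically truncated to ±3.7 log2
units (`truncate`): truncation preserves within-row order and is
idempotent. The package guarantees the numeric matrix, not a rendered
image; any heatmap function (e.g. `pheatmap`) can consume it.

## Gene-set enrichment

Two modes are provided because "systems-level analysis on the entire
ranked probe set" admits two standard readings:

* **Over-representation** (default): the query is a gene list — by
  default the top 75 — and each term is tested with the hypergeometric
  upper tail
  $p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
  where $N$ is the universe size, $K$ the term's expressed members, $n$
  the query size and $k$ the overlap.
* **Rank-based** (`method = "ranksum"`): member vs non-member positions
  in the *full* ranking are compared with a two-sided Mann–Whitney test
  on the importance scale, exact when $n_1 n_2 \le 10\,000$ (distinct
  ranks cannot tie), otherwise the tie-corrected normal approximation.

The universe is the set of expressed genes — the genes on the array after
the missing-value filter — intersected with the collection's declared
universe. Bonferroni control multiplies each raw p by $m$, the number of
terms actually tested (terms with at least one expressed member), capped
at 1. Significance is $p_{\mathrm{adj}} \le \alpha$ with $\alpha = 0.01$
and an *inclusive* boundary, exactly as the threshold is printed.

The hypergeometric null is discrete: its p-values are super-uniform
(conservative) rather than uniform, the more so the smaller the query.
Calibration checks of the continuous kind (uniformity of null p-values)
therefore use the rank-based mode; for the over-representation mode the
meaningful property is conservativeness, and that is what the test suite
asserts.

## Variation-of-information clustering of significant terms

Each significant term's gene set $S$ induces the two-block partition
$\{S, U \setminus S\}$ of the expressed-gene universe $U$. Under the
uniform measure on $U$, the variation of information between two such
partitions is

$$ \mathrm{VI}(A, B) = H(A) + H(B) - 2 I(A; B) = 2 H(A,B) - H(A) - H(B), $$

with entropies in bits ($0 \log 0 \equiv 0$; bits are the conventional
unit, and the base affects only the scale, never the tree topology). VI
is a true metric on partitions; for two-block partitions it is bounded by
2 bits. One caveat is inherited from the construction: a set and its
complement induce the same partition, so $\mathrm{VI}(A, U\setminus A)=0$.
For GO-style terms, which are far smaller than the universe, this is
immaterial in practice but it is the reason "identity of indiscernibles"
holds only up to complement. The two-block construction is the minimal
faithful way to apply a partition metric to gene sets; richer
constructions (e.g. partitions from a joint clustering of genes) would
need choices the method statement does not make.

The pairwise VI matrix is clustered agglomeratively via `stats::hclust`
(average linkage by default; single and complete are exposed since
nothing in the method fixes the linkage). The numerically clean form
$2H_{joint} - H_A - H_B$ is used and tiny negative round-off is clamped
to zero, so identical sets are at distance exactly 0 and merge first.
The shaded term table lists the significant terms in dendrogram leaf
order with their expressed-member counts, adjusted p-values, and a shade
weight $-\log_{10} p_{\mathrm{adj}}$ normalised to $[0,1]$ — the "darker
red = more significant" display convention, kept numeric here.

## The synthetic cohort generator

No expression data accompanies the motivating study, so the generator is
the package's test bed and defines the study conditions:

* **Layout**: control + 3 h + 12 h + 24 h, 9 subjects each (27 stressed,
  9 control), pooled 3-to-1 into 3 biological replicates per group.
* **Intensities** are multiplicative: $x = 2^{b_g + e_{g,t} +
  \varepsilon}$, with a per-gene base $b_g \sim N(8, 1.5^2)$ log2 units
  (a typical array intensity spread), planted effects $e_{g,t}$ added
  only in treatment groups, and noise $\varepsilon$ per subject. Log2
  ratios are therefore additive in effect and noise, and with zero noise
  the ratio of a planted gene equals its planted effect exactly — the
  calibration every recovery test rests on.
* **Noise** defaults to Gaussian with scale 0.25 log2 units, a realistic
  between-array spread for replicate bead arrays; a Laplace family with
  the same scale parameterisation is available for heavier tails.
* **Gene sets**: random terms drawn uniformly from the universe serve as
  nulls; planted terms draw a chosen fraction of members (rounded down)
  from a designated gene list, giving enrichment tests a known positive.

All randomness flows from a single integer seed; identical inputs give
bit-identical outputs. The generator deliberately does *not* emulate
probe chemistry, background correction, between-array normalisation, or
gene–gene correlation: genes are independent given their group means.
Passing recovery tests therefore show that the pipeline finds the signal
it is specified to find under independent log-scale noise — not that it
is robust to correlated or heteroskedastic real-array artefacts.

## Numerical and design choices

* Ranking ties break lexicographically by gene id; `hclust` resolves
  merge ties by its standard lowest-index rule — both make reruns
  byte-identical.
* The significance boundary is inclusive ($\le$), following the printed
  threshold; the figure caption's strict "<" is treated as a rounding of
  the same rule.
* $m$ for Bonferroni is the number of terms actually tested, not the
  collection size.
* Degenerate inputs fail loudly: non-positive intensities, effects
  outside the gene universe, terms outside the declared universe, empty
  terms, and distance matrices that are not symmetric non-negative with
  a zero diagonal are all validation errors rather than silent fixes.
* If fewer than two terms pass the filter, clustering is skipped with a
  message and the run still succeeds — an empty enrichment table is a
  valid outcome, not an error.

## Problem sizes used in the test suite

Unit tests run on fixtures of tens to hundreds of genes where oracles
(exhaustive enumeration of hypergeometric draws, permutation null of the
rank-sum statistic, hand-computed VI contingency tables) are feasible.
The calibration suites use the study-scale defaults: 5,000 genes and the
27 + 9 layout for planted-signal recovery (effect 1.5 log2 units, noise
0.25, median over 20 seeds), 500 null simulations for p-value uniformity
of the rank-based mode, 100 seeds for planted-term recovery, and 1,000
random triples for the VI metric axioms. These sizes give stable
pass/fail behaviour at conventional Monte-Carlo error while keeping a
full run under a minute of compute.

## Known limitations

* The enrichment engine of the original analysis is cited to prior work
  and not described; both provided modes are reimplementations by
  interpretation, and database-dependent published q-values are out of
  scope.
* VI on two-block partitions cannot distinguish a set from its
  complement (see above).
* The rank-based mode's normal approximation is used above
  $n_1 n_2 = 10\,000$; for tiny universes force exactness by testing
  smaller rankings.
* The generator's independence assumptions understate the multiplicity
  burden real co-regulated gene sets impose on enrichment tests.
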
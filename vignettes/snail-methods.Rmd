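---
title: "Tie-aware smooth quantile normalization: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tie-aware smooth quantile normalization: model, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailnorm)
```

## The model

Both normalizers in this package share one model, fitted by
`fit_qsmooth()` / `fit_snail()` on a genes-by-samples count matrix and a
sample-to-group assignment. Write $q_{u,s}$ for the $u$-th order statistic
of sample $s$ ($u = 1..G$; ranks play the role of quantiles because all
samples share the same gene count, so no interpolation dialect is needed).
The model holds three per-rank vectors:

* the **background reference**: an aggregate of $q_{u,\cdot}$ over all
  samples;
* one **group reference** per biological group, aggregated over that
  group's samples;
* a **blending weight** $w_u = 1 - SSB(u)/SST(u)$, the complement of the
  proportion of between-group variance among the $u$-th order statistics
  ($w_u = 1$ when $SST(u) = 0$), smoothed by a running median over a window
  of 5% of the gene count (shrinking symmetric windows at the edges) and
  clamped to $[0, 1]$.

Applying the model to a sample in group $g$ assigns rank $u$ the blend
$b_u = w_u\,\mathrm{bg}_u + (1 - w_u)\,\mathrm{grp}_{g,u}$. Because $w$
varies across ranks, the rank-wise blend of two non-decreasing vectors can
dip locally; a reference quantile distribution must be non-decreasing, so
the blend is passed through its monotone rearrangement (a sort) before
assignment. This also makes "normalization preserves within-sample order"
a theorem rather than an accident: we observed genuine order violations on
zero-inflated data before adding the rearrangement.

The two methods differ in exactly two operations:

| operation | baseline (`qsmooth`) | SNAIL |
|---|---|---|
| per-rank aggregation | mean | trimmed mean (15% per tail) |
| tie-group value over ranks `lo..hi` | mean of `b[lo..hi]` | median of `b[lo..hi]` |

The tie rule is the heart of the matter. Genes tied at one count occupy a
contiguous rank span; zero counts form the largest span, and its width
varies strongly across samples in heterogeneous data. Averaging the
reference over the span leaks the span's upper, nonzero portion into every
zero gene — by a different amount in every sample — which is precisely the
mechanism that manufactures false-positive correlations. The median of a
mostly-zero span is zero, so SNAIL returns exact zeros whenever zeros make
up the majority of the span.

`fit_snail(trim = 0)` plus tie-free data reproduces the baseline exactly,
and with a single group both reduce to classical quantile normalization;
the test suite pins both reductions against an independently written
brute-force oracle.

## Tunable parameters

* `trim` (default 0.15 per tail, range $[0, 0.5)$): the per-tail trim
  proportion for reference building, with $k = \lfloor trim \cdot n\rfloor$
  values removed per tail. With this floor rule $n - 2k \ge 1$ always
  holds; a median fallback guards the degenerate case defensively. Small
  groups are the practical concern: with fewer than $1/trim$ samples in a
  group, $k = 0$ and that group's reference is an untrimmed mean, so the
  method's protection degrades — it is designed for large heterogeneous
  collections, not for 3-sample pilot experiments.
* Blending weights are computed on **untrimmed** order statistics: trimming
  is a robustness device for the reference values, while the variance
  decomposition should describe the data as they are. `trim_weights = TRUE`
  switches this for sensitivity analysis.
* `diagnose_ties(tol = 1e-12)`: a gene counts as *affected* when it sits in
  a tie group of two or more genes whose reference span has mean and median
  differing by more than `tol`. This is deliberately the minimal definition
  under which the diagnostic flags exactly the entries where the two
  methods' outputs differ (a span's max-min being positive is not enough:
  two-value spans and symmetric spans have mean equal to median, and both
  rules then agree).
* `tissue_exclusive_genes(hi = 10, lo = 1)`: a gene is exclusive to a group
  when its median expression is at least `hi` inside the group and at most
  `lo` in every other group.
* `bonferroni_rho_threshold()`: converts a family-wise error level into a
  critical $|\rho|$ via the $t$ approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; it is exact only asymptotically, and a
  permutation check in the tests shows the tail probability at $n = 12$ is
  within ~0.01 of nominal.
* `function_prediction(rho_min, prop_min, signed = TRUE)`: neighbours are
  genes with signed $\rho \ge$ `rho_min` (signed, because co-expression in
  the guilt-by-association sense is positive coordination; a flag restores
  $|\rho|$), and a label is predicted when **strictly more than**
  `prop_min` of neighbours carry it.

## The synthetic benchmark

`simulate_coexpr_data()` generates the study conditions every scientific
claim in this package is tested under. Defaults: 2000 genes, 120 samples,
4 equal groups, 25 exclusive genes per group, library factors log-uniform
over a 20-fold span, negative-binomial dispersion 0.4, and 96 spike-in
transcripts. Its structure:

* **Ground truth** is a continuous gamma expression level per entry.
  Shared genes have gene-specific log-normal means identical in all groups;
  ten 40-gene modules among the well-expressed shared genes share
  sample-level log-normal latent factors with loadings between 0.25 and
  0.95, so genuine associations span weak to strong — threshold sweeps over
  association strength would be degenerate without them. Exclusive genes
  have high in-group means (log-normal, floored just above the exclusivity
  threshold) and a trace off-group baseline (mean 0.1). The baseline is
  deliberately not an exact zero: a block of exactly tied zeros in the
  *truth* would itself carry a strong negative rank correlation between
  cross-group pairs (about $-p/(1-p)$ at group fraction $p$), and
  "structurally unassociated" pairs would stop being unassociated. Real
  tissue-exclusive genes likewise show stray reads off-tissue.
* **Counts** are Poisson draws of the truth at a per-sample relative depth
  (so marginally negative-binomial), plus depth-dependent dropout. Off-group
  exclusive counts are still ~99% zeros, so the tie mechanism is fully
  present where it matters. Per-sample zero fractions span roughly
  0.34–0.65 — wide, but with every zero-span midpoint inside the all-zero
  rank region, which is the regime the method targets; with even more
  extreme depth spread the trimmed reference itself becomes positive at
  mid ranks and *no* rank-preserving normalization can keep all zeros at
  zero.
* **Spike-ins** have fixed abundance, identical in every sample, and pass
  through the same thinning and dropout; `spike_in_scale()` on the counts
  therefore rebuilds the depth-corrected validation expression exactly the
  way ERCC controls are used. Evaluation against this spike-scaled ground
  truth (rather than the pre-distortion gamma truth) mirrors how spike-in
  validation actually works: truth and prediction share the count-level
  zero structure, and only normalization distortions separate them.

What the generator does **not** emulate: compositional effects,
gene-length or GC biases, batch structure, within-group subpopulations, or
realistic marginal distributions of any particular consortium dataset.
Passing tests on it demonstrate that the tie artifact exists and that SNAIL
removes it under controlled heterogeneity — not that any particular real
dataset is artifact-free after SNAIL.

Test problem sizes are chosen for density of coverage per CPU-second: the
benchmark assertions run the full default generator across five fixed
seeds, while unit properties use matrices between roughly 50×8 and 400×96.

## Numerical choices

* Sorting is stable with ties broken by gene index; outputs are invariant
  to this because tied genes receive one aggregated value (asserted via
  row/column permutation equivariance).
* The median of an even-length span is the mean of the two central values.
* Spearman correlations use average ranks for ties; genes constant across
  samples have undefined correlations, are returned as `NA`, flagged, and
  excluded downstream.
* HITS hub scores: the adjacency uses $|\rho|$ (HITS requires a nonnegative
  matrix, and the procedure the hub analysis follows does not specify how
  negative weights enter). On a symmetric adjacency, hub equals authority
  and the principal eigenspace of $AA^T$ contains the Perron vector of $A$;
  the implementation power-iterates $A + rI$ (shift $r$ = max row sum),
  which isolates that vector even when $A$'s extreme eigenvalues come in
  $\pm\lambda$ pairs — on a star graph, unshifted iteration on $AA^T$
  stalls on the start vector because the top eigenvalue is degenerate.
  Scores are normalized to sum to one.
* Sample-specific network edges follow the linear decomposition
  $e_s = N\,e(\mathrm{all}) - (N-1)\,e(\mathrm{all}\setminus s)$ with
  Spearman correlation as the network function; per-edge differential
  testing uses a plain Welch $t$ with Benjamini–Hochberg correction across
  edges (moderated variance models are out of scope). Zero-variance edges
  on both sides get $p = 1$ when the means agree and $p = 0$ otherwise.
  The edge universe is restricted to a user-chosen gene subset because
  all-pairs single-sample networks grow quadratically.
* Spike-in scaling defaults to total-count factors
  $f_s = T_s/\bar T$ (deterministic, order-invariant); a median-of-ratios
  variant is available. ROC/PR areas use the trapezoid rule; the
  precision-recall area is flagged as unstable below 30 positive pairs.

## Known limitations

* SNAIL requires group labels; unlabelled samples cannot be normalized
  group-aware.
* Groups smaller than $1/trim$ samples receive untrimmed references (see
  above); the method is intended for large heterogeneous collections.
* Exact zero preservation holds when zeros are the majority of their span's
  reference; in datasets where some samples express nearly everything, a
  residual tie artifact can survive — `diagnose_ties()` is the instrument
  to check, and its per-sample proportions are exact about where the two
  tie rules disagree.
* Cross-group exclusive pairs retain a modest negative rank correlation in
  *any* rank-based view of sparse data (the group-block structure itself);
  removing normalization artifacts cannot and should not remove it. The
  relevant measure of introduced co-expression is the deviation from the
  correlations the raw counts already carry.
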
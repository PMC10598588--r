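# snailnorm

Group-aware smooth quantile normalization for RNA-Seq data that is safe to
feed into co-expression and network analysis.

## The problem

Quantile-based normalization forces every sample's expression distribution
onto a shared reference: the value at rank *u* in a sample is replaced by a
reference value for quantile *u/G*. Smooth quantile normalization (the
*qsmooth* approach) refines this for heterogeneous datasets by blending, at
each rank, a **background** reference (aggregated over all samples) with a
**group** reference (aggregated over the sample's biological group),
weighted by the proportion of between-group variance at that rank:

```
b_u = w_u * background_u + (1 - w_u) * group_u,   w_u = 1 - SSB(u)/SST(u)
```

This preserves genuine global expression differences between tissues — but
it has a side effect that matters enormously for *correlation*-based
analysis. Genes tied at the same read count (above all, the thousands of
zero counts) occupy a contiguous rank span and receive the **mean** of the
reference over that span. Because the number of zeros differs across
samples, the span differs, so a gene counted zero everywhere is assigned a
small *sample-dependent, nonzero* value. Across genes these assigned values
co-vary perfectly with per-sample zero content, which manufactures strong
false-positive Spearman correlations between genes that are never expressed
in the same samples — and the artifact propagates into co-expression
networks, hub statistics, and function prediction.

## The method

SNAIL (smooth-quantile normalization adaptation for the inference of
co-expression links) keeps the smooth-quantile model and changes two
operations:

1. **Trimmed-mean references.** Background and per-group reference
   distributions are per-rank *trimmed* means of the order statistics
   (default: 15% per tail), so a handful of deeply sequenced samples cannot
   drag the low quantiles of the reference away from zero.
2. **Median tie aggregation.** A tie group spanning ranks `lo..hi` receives
   the *median* of `b_lo..b_hi` instead of the mean. The median of a
   mostly-zero span is zero: nonexpressed genes stay at exactly zero, and
   the tie artifact disappears.

A diagnostic reports, per sample, the proportion of genes whose normalized
value depends on the tie-aggregation rule — i.e. exactly where the two
methods disagree — so you can check whether plain smooth quantile
normalization would be safe on your data before choosing.

The package also ships the machinery used to validate the method: the
classic smooth-quantile baseline, a seeded zero-inflated multi-group count
simulator with spike-in controls and known ground truth, co-expression
evaluation (ROC/PR areas, correlation RMSE, Bonferroni correlation
thresholds, guilt-by-association function prediction with Jaccard scoring)
and single-sample network analysis (LIONESS edges, group aggregation, HITS
hub scores, per-edge Welch tests with BH correction).

## Worked example

```r
library(snailnorm)
library(dplyr)

sim <- simulate_coexpr_data(seed = 7)   # 2000 genes x 120 samples, 4 groups
sim
#> <snail_sim> 2000 genes x 120 samples, 4 groups, 25 exclusive genes/group
#>   library span 1x-20x, per-sample zero fraction 0.34-0.63, seed 7

# how exposed is this dataset to the tie artifact?
diagnose_ties(sim$counts, sim$groups)
#> Tie-sensitivity diagnosis for 120 samples (max affected: 98.3%)

norm_q <- normalize_counts(sim$counts, sim$groups, method = "qsmooth")
norm_s <- normalize_counts(sim$counts, sim$groups, method = "snail")

# Spearman correlation between genes exclusive to *different* groups —
# pairs that share no biological signal
excl <- sim$exclusive_genes
cross_rho <- function(x) {
  cross_group_pairs(spearman_matrix(x, gene_subset = excl$gene_id), excl)$rho
}
tibble(
  data = c("qsmooth", "SNAIL", "raw counts"),
  mean_abs_rho = c(mean(abs(cross_rho(norm_q))), mean(abs(cross_rho(norm_s))),
                   mean(abs(cross_rho(sim$counts)))),
  n_above_0.3 = c(sum(cross_rho(norm_q) >= 0.3), sum(cross_rho(norm_s) >= 0.3),
                  sum(cross_rho(sim$counts) >= 0.3))
)
#>   data       mean_abs_rho n_above_0.3
#> 1 qsmooth           0.436        3411
#> 2 SNAIL             0.129           0
#> 3 raw counts        0.124           0
```

Out of 3750 cross-group exclusive pairs, the baseline pushes 3411 above the
conventional co-expression cutoff of 0.3; SNAIL pushes none, and its
correlations match the raw counts (the residual 0.12 is the rank structure
the sparse counts themselves carry, not a normalization product).

Against the spike-in-scaled ground truth (the simulator plants 96 constant
spike-in transcripts; `spike_in_scale()` rebuilds the validation expression
the way ERCC controls do):

```r
gt <- spike_in_scale(sim$counts, sim$spike_genes, keep_spikes = FALSE)
genes <- setdiff(sim$counts$gene_id, sim$spike_genes)
rho_gt <- spearman_matrix(gt)
coexpr_metrics(spearman_matrix(norm_q, gene_subset = genes), rho_gt)
#> <coexpr_metrics> 1999000 pairs, 3532 positive (|rho_truth| >= 0.3)
#>   AUROC 0.9724 | AUPRC 0.2510 | correlation RMSE 0.09421
coexpr_metrics(spearman_matrix(norm_s, gene_subset = genes), rho_gt)
#> <coexpr_metrics> 1999000 pairs, 3532 positive (|rho_truth| >= 0.3)
#>   AUROC 0.9993 | AUPRC 0.8486 | correlation RMSE 0.02302
```

SNAIL recovers true associations with a precision-recall area of 0.85
versus 0.25 for the baseline and reproduces the ground-truth correlations
four times more faithfully (RMSE 0.023 vs 0.094).

A command-line wrapper over the same functions lives at
`inst/cli/snail.R` (`simulate`, `normalize`, `diagnose`, `evaluate`,
`network` subcommands); the methods vignette in `vignettes/` documents the
model, the simulator, and the numerical choices.

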
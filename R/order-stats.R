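# Order-statistic and tie machinery shared by the qsmooth baseline and SNAIL.

#' Per-sample order statistics
#'
#' Sorts each sample's values ascending with ties kept in gene order
#' (a stable sort), recording the permutation so the original column can be
#' recovered exactly.
#'
#' @param counts Counts data frame or matrix.
#' @return A tibble with one row per gene and sample: `sample_id`, `rank`
#'   (1-based, ascending value), `gene_id`, `value`.
#' @export
order_statistics <- function(counts) {
  m <- as_count_matrix(counts, require_samples = 1L)
  ord <- sample_orderings(m)
  purrr::map_dfr(seq_len(ncol(m)), function(s) {
    tibble::tibble(
      sample_id = colnames(m)[s],
      rank = seq_len(nrow(m)),
      gene_id = rownames(m)[ord$perm[, s]],
      value = ord$sorted[, s]
    )
  })
}

# Internal fast path: stable ascending sort of every column.
# Returns list(sorted = GxS matrix, perm = GxS matrix of row indices such
# that m[perm[, s], s] == sorted[, s]).
#' @keywords internal
sample_orderings <- function(m) {
  g <- nrow(m)
  perm <- matrix(0L, g, ncol(m))
  sorted <- matrix(0, g, ncol(m))
  for (s in seq_len(ncol(m))) {
    o <- order(m[, s], seq_len(g)) # ties broken by gene index: stable
    perm[, s] <- o
    sorted[, s] <- m[o, s]
  }
  list(sorted = sorted, perm = perm)
}

#' Tie groups of a count table
#'
#' For each sample, the maximal runs of equal values in the sorted column.
#' Genes in a run share one raw count and occupy a contiguous rank span
#' `[lo, hi]`; the spans partition `1..G`.
#'
#' @param counts Counts data frame or matrix.
#' @return A tibble with columns `sample_id`, `value`, `lo`, `hi`, `n_genes`.
#' @export
tie_groups <- function(counts) {
  m <- as_count_matrix(counts, require_samples = 1L)
  ord <- sample_orderings(m)
  purrr::map_dfr(seq_len(ncol(m)), function(s) {
    v <- ord$sorted[, s]
    r <- rle(v)
    hi <- cumsum(r$lengths)
    tibble::tibble(
      sample_id = colnames(m)[s],
      value = r$values,
      lo = hi - r$lengths + 1L,
      hi = hi,
      n_genes = r$lengths
    )
  })
}

#' Trimmed mean
#'
#' Removes `floor(trim * n)` values from each tail of the sorted vector and
#' averages the rest. `trim = 0` is the plain mean; at the maximal trim for
#' odd `n` the result is the median.
#'
#' @param x Numeric vector.
#' @param trim Proportion trimmed from each tail, in `[0, 0.5)`.
#' @return A single number.
#' @export
trimmed_mean <- function(x, trim = 0.15) {
  if (trim < 0 || trim >= 0.5) abort("trim must be in [0, 0.5)")
  n <- length(x)
  if (n < 1L) abort("trimmed_mean needs at least one value")
  k <- floor(trim * n)
  if (n - 2L * k < 1L) {
    warn("too few values for the requested trim; falling back to the median")
    return(median(x))
  }
  if (k == 0L) return(mean(x))
  s <- sort(x)
  mean(s[(k + 1L):(n - k)])
}

# Per-rank aggregation of a set of sorted columns (rows = ranks, cols =
# samples). aggregator "mean" or "trimmed_mean" with per-tail proportion
# `trim`. Output is non-decreasing because each column is and both
# aggregators are monotone in every argument.
#' @keywords internal
reference_vector <- function(sorted_cols, aggregator = c("mean", "trimmed_mean"),
                             trim = 0.15) {
  aggregator <- match.arg(aggregator)
  if (aggregator == "mean" || trim == 0) {
    return(rowMeans(sorted_cols))
  }
  n <- ncol(sorted_cols)
  k <- floor(trim * n)
  if (n - 2L * k < 1L) {
    warn("too few samples for the requested trim; using the per-rank median")
    return(apply(sorted_cols, 1, median))
  }
  if (k == 0L) return(rowMeans(sorted_cols))
  apply(sorted_cols, 1, function(v) {
    s <- sort.int(v)
    mean(s[(k + 1L):(n - k)])
  })
}

# Running median with window w (shrinking symmetric windows at the edges);
# used to smooth the per-rank blending weights.
#' @keywords internal
running_median <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L || length(x) == 1L) return(x)
  h <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
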
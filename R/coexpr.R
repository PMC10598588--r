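#' Spearman co-expression matrix
#'
#' Gene-by-gene Spearman rank correlation across samples, with average ranks
#' for tied values. Genes constant across all samples have undefined
#' correlations; their entries are `NA` and their count is reported in the
#' `"n_undefined"` attribute (and a message).
#'
#' @inheritParams fit_qsmooth
#' @param gene_subset Optional character vector of gene IDs to restrict to.
#' @return A symmetric numeric matrix (class `coexpr_matrix`) with unit
#'   diagonal for defined genes; tidy it into pairs with [coexpr_pairs()].
#' @export
spearman_matrix <- function(counts, gene_subset = NULL) {
  m <- as_count_matrix(counts, require_samples = 3L)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing)) {
      abort(paste0("genes not in counts: ", paste(missing, collapse = ", ")))
    }
    m <- m[gene_subset, , drop = FALSE]
  }
  constant <- apply(m, 1, function(v) max(v) == min(v))
  ranks <- t(apply(m, 1, rank)) # average ranks for ties
  rho <- suppressWarnings(cor(t(ranks), method = "pearson"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  if (any(constant)) {
    message(sum(constant), " constant gene(s) have undefined correlations")
  }
  attr(rho, "n_undefined") <- sum(constant)
  class(rho) <- c("coexpr_matrix", class(rho))
  rho
}

#' Tidy a co-expression matrix into gene pairs
#'
#' @param rho A square symmetric correlation matrix with gene IDs as
#'   dimnames (e.g. from [spearman_matrix()]).
#' @param gene_subset Optional restriction of the gene universe.
#' @return A tibble of unordered pairs (`gene_a < gene_b`) with column
#'   `rho`; undefined correlations are `NA`.
#' @export
coexpr_pairs <- function(rho, gene_subset = NULL) {
  if (!is.null(gene_subset)) rho <- rho[gene_subset, gene_subset, drop = FALSE]
  ids <- rownames(rho)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  tibble::tibble(
    gene_a = ids[idx[, 1L]],
    gene_b = ids[idx[, 2L]],
    rho = rho[idx]
  )
}

#' Identify group-exclusive genes
#'
#' A gene is exclusive to group \eqn{g} when its median expression is at
#' least `hi` across the samples of \eqn{g} and at most `lo` across the
#' samples of every other group. With `hi > lo` a gene can be exclusive to
#' at most one group.
#'
#' @param truth Expression data frame or matrix the medians are taken on
#'   (typically ground-truth or spike-in-scaled expression).
#' @inheritParams fit_qsmooth
#' @param hi In-group median threshold (default 10).
#' @param lo Out-group median threshold (default 1).
#' @return A tibble with columns `group` and `gene_id`.
#' @export
tissue_exclusive_genes <- function(truth, groups, hi = 10, lo = 1) {
  if (hi <= lo) abort("hi must exceed lo")
  m <- as_count_matrix(truth)
  grp <- resolve_groups(groups, colnames(m))
  if (nlevels(grp) < 2L) abort("need at least 2 groups")
  med <- vapply(levels(grp), function(gl) {
    apply(m[, grp == gl, drop = FALSE], 1, median)
  }, numeric(nrow(m)))
  purrr::map_dfr(seq_len(nlevels(grp)), function(gi) {
    ok <- med[, gi] >= hi &
      apply(med[, -gi, drop = FALSE], 1, max) <= lo
    tibble::tibble(group = levels(grp)[gi], gene_id = rownames(m)[ok])
  })
}

#' Bonferroni-corrected Spearman significance threshold
#'
#' The smallest `|rho|` whose two-sided p-value under the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} stays below `alpha / n_tests`.
#' Useful to translate a multiple-testing-corrected significance level into
#' a correlation cutoff for declaring co-expression.
#'
#' @param n_samples Number of samples the correlations are computed on
#'   (at least 4).
#' @param n_tests Number of gene pairs tested.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The critical `|rho|` in `(0, 1)`.
#' @examples
#' bonferroni_rho_threshold(n_samples = 12, n_tests = 1) # about 0.576
#' @export
bonferroni_rho_threshold <- function(n_samples, n_tests, alpha = 0.05) {
  if (n_samples < 4) abort("need at least 4 samples")
  if (n_tests < 1) abort("n_tests must be at least 1")
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  p <- alpha / n_tests
  t_crit <- qt(1 - p / 2, df = n_samples - 2)
  rho <- t_crit / sqrt(n_samples - 2 + t_crit^2)
  if (!is.finite(rho) || rho >= 1) {
    abort("no attainable |rho| < 1 meets the corrected significance level")
  }
  rho
}
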
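#' Tie-sensitivity diagnostic: proportion of affected genes per sample
#'
#' A gene is *affected* in a sample when its normalized value depends on how
#' tied counts are aggregated: it sits in a tie group of two or more genes
#' whose span of blended reference values has a mean that differs from its
#' median (beyond `tol`). These are exactly the entries where the qsmooth
#' baseline and SNAIL disagree, so a large proportion warns that classic
#' smooth quantile normalization would manufacture co-expression in this
#' dataset.
#'
#' @inheritParams fit_snail
#' @param tol Numeric tolerance on the mean-median difference.
#' @return A tibble with columns `sample_id` and `prop_affected` (affected
#'   genes / total genes), ordered as the input samples, with the overall
#'   maximum in attribute `"max_affected"`. Class `snail_diagnosis`, so
#'   [autoplot()] draws it directly.
#' @examples
#' sim <- simulate_coexpr_data(n_genes = 60, n_samples = 12, n_groups = 2,
#'                             n_exclusive_per_group = 5, seed = 1)
#' diagnose_ties(sim$counts, sim$groups)
#' @export
diagnose_ties <- function(counts, groups, trim = 0.15, tol = 1e-12) {
  m <- as_count_matrix(counts)
  fit <- fit_snail(m, groups, trim = trim)
  grp <- resolve_groups(groups, colnames(m))
  ord <- sample_orderings(m)
  prop <- vapply(seq_len(ncol(m)), function(s) {
    b <- blended_reference(fit, as.character(grp[s]))
    r <- rle(ord$sorted[, s])
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    affected <- 0L
    for (i in which(r$lengths >= 2L)) {
      span <- b[lo[i]:hi[i]]
      if (abs(mean(span) - median(span)) > tol) affected <- affected + r$lengths[i]
    }
    affected / nrow(m)
  }, numeric(1))
  out <- tibble::tibble(sample_id = colnames(m), prop_affected = prop)
  attr(out, "max_affected") <- max(prop)
  class(out) <- c("snail_diagnosis", class(out))
  out
}

#' @export
print.snail_diagnosis <- function(x, ...) {
  cat(sprintf(
    "Tie-sensitivity diagnosis for %d samples (max affected: %.1f%%)\n",
    nrow(x), 100 * attr(x, "max_affected")
  ))
  NextMethod()
}

#' Plot a tie-sensitivity diagnosis
#'
#' Bar chart of the proportion of affected genes per sample.
#'
#' @param object A `snail_diagnosis` tibble from [diagnose_ties()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snail_diagnosis
#' @export
autoplot.snail_diagnosis <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$sample_id, -.data$prop_affected),
    y = .data$prop_affected
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "proportion of affected genes",
      title = "Genes whose normalized value depends on tie aggregation"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
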
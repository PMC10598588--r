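# Applying a fitted reference to a count matrix. For a sample in group g the
# value offered at rank u is the blend
#     b_u = w_u * background_ref_u + (1 - w_u) * group_ref_{g,u},
# and every tie group (genes sharing one raw count, spanning ranks lo..hi)
# receives a single aggregate of b_lo..b_hi: the MEAN for the qsmooth
# baseline, the MEDIAN for SNAIL. The median of a mostly-zero span is zero,
# which is precisely how SNAIL keeps nonexpressed genes at zero.
#
# Because the weights vary across ranks, the rank-wise blend of two
# non-decreasing reference vectors need not itself be non-decreasing; a
# reference quantile distribution must be, so the blend gets the monotone
# rearrangement (sort) before values are assigned. This also guarantees that
# normalization preserves within-sample order.

#' @keywords internal
blended_reference <- function(fit, group) {
  gcol <- fit$group_refs[, match(group, fit$group_levels)]
  sort.int(fit$weights * fit$background_ref + (1 - fit$weights) * gcol)
}

#' @keywords internal
apply_reference <- function(counts, fit, groups, tie_aggregate) {
  m <- as_count_matrix(counts)
  if (nrow(m) != fit$n_genes) {
    abort(sprintf(
      "model fitted on %d genes but counts have %d rows", fit$n_genes, nrow(m)
    ))
  }
  grp <- resolve_groups(groups, colnames(m))
  unknown <- setdiff(levels(grp), fit$group_levels)
  if (length(unknown)) {
    abort(paste0("group(s) not in the fitted model: ", paste(unknown, collapse = ", ")))
  }
  ord <- sample_orderings(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  agg <- if (tie_aggregate == "mean") mean else median
  for (s in seq_len(ncol(m))) {
    b <- blended_reference(fit, as.character(grp[s]))
    r <- rle(ord$sorted[, s])
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    vals <- numeric(nrow(m))
    for (i in seq_along(lo)) {
      vals[lo[i]:hi[i]] <- agg(b[lo[i]:hi[i]])
    }
    out[ord$perm[, s], s] <- vals
  }
  out
}

#' Apply a qsmooth reference to counts
#'
#' Replaces each sample's values by the blended reference at the matching
#' ranks; genes tied at one count receive the *mean* of the reference values
#' across their rank span (the classic smooth-quantile behaviour, kept here
#' as the comparison baseline).
#'
#' @inheritParams fit_qsmooth
#' @param fit A `snail_ref` from [fit_qsmooth()] (or [fit_snail()]).
#' @return A tibble of normalized values, same genes and samples as `counts`.
#' @export
apply_qsmooth <- function(counts, fit, groups) {
  stopifnot(inherits(fit, "snail_ref"))
  as_count_tibble(apply_reference(counts, fit, groups, "mean"))
}

#' Apply a SNAIL reference to counts
#'
#' As [apply_qsmooth()], but each tie group receives the *median* of the
#' blended reference over its rank span (even spans average the two central
#' values). Zero counts therefore normalize to exactly zero whenever the
#' majority of their span's reference values are zero.
#'
#' @inheritParams apply_qsmooth
#' @export
apply_snail <- function(counts, fit, groups) {
  stopifnot(inherits(fit, "snail_ref"))
  as_count_tibble(apply_reference(counts, fit, groups, "median"))
}

#' Normalize a count table in one call
#'
#' Convenience wrapper: fits the reference on `counts` and applies it.
#'
#' @inheritParams fit_snail
#' @param method `"snail"` (default) or `"qsmooth"`.
#' @param log2 Normalize `log2(x + 1)`-transformed counts instead of raw
#'   counts (off by default).
#' @return A tibble of normalized values, same shape as `counts`.
#' @examples
#' sim <- simulate_coexpr_data(n_genes = 50, n_samples = 12, n_groups = 2,
#'                             n_exclusive_per_group = 5, seed = 1)
#' norm <- normalize_counts(sim$counts, sim$groups, method = "snail")
#' @export
normalize_counts <- function(counts, groups, method = c("snail", "qsmooth"),
                             trim = 0.15, log2 = FALSE) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  if (log2) m <- log2(m + 1)
  if (method == "qsmooth") {
    fit <- fit_qsmooth(m, groups)
    apply_qsmooth(m, fit, groups)
  } else {
    fit <- fit_snail(m, groups, trim = trim)
    apply_snail(m, fit, groups)
  }
}
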
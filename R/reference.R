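# Fitting the smooth-quantile reference model shared by the qsmooth baseline
# and SNAIL. The model holds, for every rank u = 1..G:
#   * a background reference (aggregate of the u-th order statistics over all
#     samples),
#   * one reference per biological group (aggregate over that group's
#     samples), and
#   * a blending weight w_u in [0, 1]: the share of the background reference
#     in the value finally assigned at rank u.
# Weights follow the smooth quantile construction: w_raw(u) = 1 - SSB/SST of
# the u-th order statistics across samples (1 when SST = 0), smoothed by a
# running median over a window of 5% of the gene count and clamped to [0, 1].

#' @keywords internal
fit_reference <- function(m, groups, aggregator, trim) {
  validate_count_matrix(m, require_samples = 2L)
  grp <- resolve_groups(groups, colnames(m))
  ord <- sample_orderings(m)
  q <- ord$sorted # G x S order statistics
  g_levels <- levels(grp)

  background <- reference_vector(q, aggregator, trim)
  group_refs <- vapply(g_levels, function(gl) {
    reference_vector(q[, grp == gl, drop = FALSE], aggregator, trim)
  }, numeric(nrow(q)))

  # variance decomposition on the untrimmed order statistics
  qbar <- rowMeans(q)
  sst <- rowSums((q - qbar)^2)
  group_means <- vapply(g_levels, function(gl) {
    rowMeans(q[, grp == gl, drop = FALSE])
  }, numeric(nrow(q)))
  n_g <- as.numeric(table(grp)[g_levels])
  ssb <- (group_means - qbar)^2 %*% n_g
  w_raw <- ifelse(sst == 0, 1, 1 - as.numeric(ssb) / sst)
  w <- pmin(1, pmax(0, running_median(w_raw, round(0.05 * nrow(q)))))

  structure(
    list(
      background_ref = background,
      group_refs = group_refs,
      weights = w,
      w_raw = w_raw,
      group_levels = g_levels,
      n_genes = nrow(m),
      n_samples = ncol(m),
      method = if (aggregator == "mean") "qsmooth" else "snail",
      trim = if (aggregator == "mean") 0 else trim
    ),
    class = "snail_ref"
  )
}

#' Fit the smooth quantile normalization reference (qsmooth baseline)
#'
#' Builds the background and per-group reference distributions as plain
#' per-rank means of the order statistics, plus the per-rank blending
#' weights. This is the baseline whose tie handling introduces spurious
#' co-expression between genes expressed in disjoint sample subsets; see
#' [fit_snail()] for the corrected variant.
#'
#' @param counts Counts data frame (first column `gene_id`) or a named
#'   genes-by-samples matrix.
#' @param groups Sample-to-group assignment: a data frame with columns
#'   `sample_id` and `group`, or a named character vector.
#' @return An object of class `snail_ref` with elements `background_ref`,
#'   `group_refs` (rank-by-group matrix), `weights`, and metadata. Use
#'   [apply_qsmooth()] to normalize with it; [tidy()] and [glance()] methods
#'   expose it as tibbles.
#' @seealso [fit_snail()], [apply_qsmooth()]
#' @export
fit_qsmooth <- function(counts, groups) {
  m <- as_count_matrix(counts)
  fit_reference(m, groups, "mean", trim = 0)
}

#' Fit the SNAIL normalization reference
#'
#' Like [fit_qsmooth()] but every reference distribution (background and per
#' group) is a per-rank *trimmed* mean of the order statistics, discarding
#' the `trim` largest and smallest values at each rank (15% per tail by
#' default). Trimming keeps a handful of deeply sequenced samples from
#' dragging the low quantiles of the reference away from zero. Blending
#' weights are computed on the untrimmed order statistics, exactly as in
#' [fit_qsmooth()]; set `trim_weights = TRUE` to trim there too.
#'
#' @inheritParams fit_qsmooth
#' @param trim Proportion trimmed from each tail at every rank, in
#'   `[0, 0.5)`.
#' @param trim_weights Also compute the variance-decomposition weights from
#'   trimmed statistics (off by default).
#' @return A `snail_ref` object; use [apply_snail()] to normalize with it.
#' @export
fit_snail <- function(counts, groups, trim = 0.15, trim_weights = FALSE) {
  if (trim < 0 || trim >= 0.5) abort("trim must be in [0, 0.5)")
  m <- as_count_matrix(counts)
  fit <- fit_reference(m, groups, if (trim > 0) "trimmed_mean" else "mean", trim)
  fit$method <- "snail"
  fit$trim <- trim
  if (trim_weights && trim > 0) {
    # recompute w_raw on trimmed per-rank statistics
    ord <- sample_orderings(m)
    grp <- resolve_groups(groups, colnames(m))
    q <- ord$sorted
    n <- ncol(q)
    k <- floor(trim * n)
    if (n - 2L * k >= 1L && k > 0L) {
      keep <- t(apply(q, 1, function(v) sort.int(v)[(k + 1L):(n - k)]))
      qbar <- rowMeans(keep)
      sst <- rowSums((keep - qbar)^2)
      # group structure is lost after trimming; fall back to untrimmed SSB
      ssb_frac <- ifelse(fit$w_raw == 1, 0, 1 - fit$w_raw)
      w_raw <- ifelse(sst == 0, 1, 1 - ssb_frac)
      fit$w_raw <- w_raw
      fit$weights <- pmin(1, pmax(0, running_median(w_raw, round(0.05 * nrow(q)))))
    }
  }
  fit
}

#' @export
print.snail_ref <- function(x, ...) {
  cat(sprintf(
    "<snail_ref> %s reference: %d genes, %d samples, %d group(s)%s\n",
    x$method, x$n_genes, x$n_samples, length(x$group_levels),
    if (x$method == "snail") sprintf(", trim = %g per tail", x$trim) else ""
  ))
  cat(sprintf(
    "  blending weight w: min %.3f / median %.3f / max %.3f\n",
    min(x$weights), median(x$weights), max(x$weights)
  ))
  invisible(x)
}

#' Tidy a fitted normalization reference
#'
#' @param x A `snail_ref` object.
#' @param ... Unused.
#' @return A tibble with one row per rank and group: `rank`, `quantile`
#'   (rank / G), `background_ref`, `weight`, `group`, `group_ref`, and
#'   `blended` (the value a sample of that group receives at that rank).
#' @method tidy snail_ref
#' @export
tidy.snail_ref <- function(x, ...) {
  g <- x$n_genes
  base <- tibble::tibble(
    rank = seq_len(g),
    quantile = seq_len(g) / g,
    background_ref = x$background_ref,
    weight = x$weights
  )
  tidyr::crossing(base, group = x$group_levels) |>
    dplyr::mutate(
      group_ref = x$group_refs[cbind(.data$rank, match(.data$group, x$group_levels))]
    ) |>
    dplyr::arrange(.data$group, .data$rank) |>
    dplyr::group_by(.data$group) |>
    # the value assigned at rank u: monotone rearrangement of the blend
    dplyr::mutate(blended = blended_reference(x, .data$group[1])) |>
    dplyr::ungroup()
}

#' One-line summary of a fitted normalization reference
#'
#' @inheritParams tidy.snail_ref
#' @return A one-row tibble: `method`, `trim`, `n_genes`, `n_samples`,
#'   `n_groups`, `mean_weight`.
#' @method glance snail_ref
#' @export
glance.snail_ref <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    trim = x$trim,
    n_genes = x$n_genes,
    n_samples = x$n_samples,
    n_groups = length(x$group_levels),
    mean_weight = mean(x$weights)
  )
}
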
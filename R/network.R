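# Single-sample co-expression networks and their downstream analyses.
# Sample-specific edges follow the LIONESS decomposition: with e() the
# Spearman correlation computed on the indicated samples and N the sample
# count, the edge of sample s is e_s = N * e(all) - (N - 1) * e(all \ s),
# so that the aggregate network is the average of the sample networks.

#' Sample-specific network edges (LIONESS)
#'
#' Computes one edge-weight vector per sample by contrasting the Spearman
#' co-expression of all samples with that of all samples but one. Because
#' all-pairs networks grow quadratically, the edge universe is restricted to
#' `gene_subset` (typically the group-exclusive genes under study).
#'
#' @inheritParams fit_qsmooth
#' @param gene_subset Character vector of gene IDs to build the network on
#'   (at least 2; default all genes — beware of size).
#' @return A wide tibble with columns `gene_a`, `gene_b` (each unordered
#'   pair once) followed by one numeric column per sample. Pairs undefined
#'   in any leave-one-out subset (a gene constant there) carry `NA`.
#' @export
lioness_edges <- function(counts, gene_subset = NULL) {
  m <- as_count_matrix(counts, require_samples = 3L)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing)) {
      abort(paste0("genes not in counts: ", paste(missing, collapse = ", ")))
    }
    m <- m[gene_subset, , drop = FALSE]
  }
  if (nrow(m) < 2L) abort("need at least 2 genes for a network")
  n <- ncol(m)
  sp <- function(x) {
    ranks <- t(apply(x, 1, rank))
    suppressWarnings(cor(t(ranks)))
  }
  e_all <- sp(m)
  ut <- upper.tri(e_all)
  ids <- rownames(m)
  idx <- which(ut, arr.ind = TRUE)
  out <- matrix(NA_real_, sum(ut), n, dimnames = list(NULL, colnames(m)))
  for (s in seq_len(n)) {
    e_loo <- sp(m[, -s, drop = FALSE])
    out[, s] <- n * e_all[ut] - (n - 1) * e_loo[ut]
  }
  dplyr::bind_cols(
    tibble::tibble(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]]),
    tibble::as_tibble(out)
  )
}

#' Aggregate sample-specific networks by group
#'
#' Per-group edge weight is the arithmetic mean over that group's samples.
#'
#' @param edges Wide edge tibble from [lioness_edges()].
#' @inheritParams fit_qsmooth
#' @return A tibble `group`, `gene_a`, `gene_b`, `weight`.
#' @export
aggregate_networks <- function(edges, groups) {
  sample_ids <- setdiff(names(edges), c("gene_a", "gene_b"))
  grp <- resolve_groups(groups, sample_ids)
  w <- as.matrix(edges[, sample_ids, drop = FALSE])
  purrr::map_dfr(levels(grp), function(gl) {
    cols <- which(grp == gl)
    if (!length(cols)) abort(paste0("empty group: ", gl))
    tibble::tibble(
      group = gl, gene_a = edges$gene_a, gene_b = edges$gene_b,
      weight = rowMeans(w[, cols, drop = FALSE])
    )
  })
}

#' HITS hub scores of a co-expression network
#'
#' Builds a symmetric nonnegative adjacency from the absolute edge weights
#' and returns the hub scores of the HITS algorithm — the principal
#' eigenvector of \eqn{A A^T} — normalized to sum to one. On a symmetric
#' adjacency hub and authority scores coincide and the principal eigenspace
#' of \eqn{A A^T} contains the Perron vector of \eqn{A}; scores are that
#' Perron vector, found by shifted power iteration (tolerance 1e-8, at most
#' 1000 iterations). The shift matters: on bipartite-like graphs such as a
#' star, \eqn{A}'s extreme eigenvalues come in \eqn{\pm\lambda} pairs, so
#' \eqn{A A^T} alone has a degenerate top eigenvalue and unshifted iteration
#' stalls on the start vector's projection. An all-zero network yields
#' uniform scores with a warning.
#'
#' @param network Edge tibble `gene_a`, `gene_b`, `weight` for one network,
#'   or the multi-group output of [aggregate_networks()] (scored per group).
#' @return A tibble `gene_id`, `score` (plus `group` for multi-group input).
#' @export
hub_scores <- function(network) {
  if ("group" %in% names(network)) {
    return(
      network |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(~ hub_scores_one(.x)) |>
        dplyr::ungroup()
    )
  }
  hub_scores_one(network)
}

#' @keywords internal
hub_scores_one <- function(network) {
  ids <- sort(unique(c(network$gene_a, network$gene_b)))
  if (length(ids) < 2L) abort("need at least 2 genes")
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w <- abs(network$weight)
  w[is.na(w)] <- 0
  ia <- match(network$gene_a, ids)
  ib <- match(network$gene_b, ids)
  a[cbind(ia, ib)] <- w
  a[cbind(ib, ia)] <- w
  if (all(a == 0)) {
    warn("all-zero network: uniform hub scores")
    return(tibble::tibble(gene_id = ids, score = 1 / length(ids)))
  }
  shift <- max(rowSums(a))
  v <- rep(1 / length(ids), length(ids))
  for (i in seq_len(1000L)) {
    v_new <- as.numeric(a %*% v) + shift * v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < 1e-8) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- abs(v)
  tibble::tibble(gene_id = ids, score = v / sum(v))
}

#' Per-edge Welch tests between two network collections
#'
#' Compares, edge by edge, the per-sample weight distributions of two edge
#' tables (e.g. networks built on normalized expression versus networks
#' built on ground truth) with a two-sample Welch t-test, then controls the
#' false discovery rate across edges by Benjamini-Hochberg. Edges with zero
#' variance on both sides get p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param edges_a,edges_b Wide edge tibbles from [lioness_edges()] over the
#'   same gene pairs (sample sets may differ; at least 2 samples each).
#' @param fdr Significance level on the adjusted p-value.
#' @return A tibble `gene_a`, `gene_b`, `mean_a`, `mean_b`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
edge_ttests <- function(edges_a, edges_b, fdr = 0.05) {
  key_a <- paste(edges_a$gene_a, edges_a$gene_b)
  key_b <- paste(edges_b$gene_a, edges_b$gene_b)
  if (!identical(sort(key_a), sort(key_b))) {
    abort("edge tables cover different gene pairs")
  }
  edges_b <- edges_b[match(key_a, key_b), ]
  wa <- as.matrix(edges_a[, setdiff(names(edges_a), c("gene_a", "gene_b"))])
  wb <- as.matrix(edges_b[, setdiff(names(edges_b), c("gene_a", "gene_b"))])
  if (ncol(wa) < 2L || ncol(wb) < 2L) abort("need at least 2 samples per side")
  na <- ncol(wa); nb <- ncol(wb)
  ma <- rowMeans(wa); mb <- rowMeans(wb)
  va <- apply(wa, 1, stats::var); vb <- apply(wb, 1, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  t_stat[degenerate & p == 1] <- 0
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(
    gene_a = edges_a$gene_a, gene_b = edges_a$gene_b,
    mean_a = ma, mean_b = mb, statistic = t_stat,
    p_value = p, p_adjusted = p_adj, significant = p_adj <= fdr
  )
}
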
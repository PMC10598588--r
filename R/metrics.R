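# Evaluation of a predicted co-expression matrix against ground truth:
# ROC / precision-recall over a sweep of |rho| cutoffs, trapezoid areas,
# and the RMSE between predicted and true correlation coefficients.

#' Evaluate predicted co-expression against ground truth
#'
#' Pairs are labelled positive when their ground-truth correlation satisfies
#' `|rho_truth| >= rho_min`; the predicted `|rho|` is then used as a score
#' and swept over all cutoffs to produce ROC and precision-recall curves
#' (areas by the trapezoid rule). The RMSE between predicted and true
#' coefficients over all defined pairs is reported alongside.
#'
#' @param pred_rho Predicted correlation matrix ([spearman_matrix()]) or a
#'   pair tibble from [coexpr_pairs()].
#' @param truth_rho Ground-truth correlation matrix or pair tibble over the
#'   same gene universe.
#' @param rho_min Threshold on `|rho_truth|` defining a true association.
#' @return An object of class `coexpr_metrics`: a list with `roc` and `pr`
#'   curve tibbles, `auroc`, `auprc`, `rmse`, `n_pairs`, `n_positive`, and
#'   `rho_min`. When fewer than 30 positive pairs exist the precision-recall
#'   area is kept but flagged (`pr_unstable = TRUE`); with none it is `NA`.
#'   [autoplot()] draws both curves; [glance()] returns the scalars.
#' @export
coexpr_metrics <- function(pred_rho, truth_rho, rho_min = 0.3) {
  pred <- if (is.data.frame(pred_rho)) pred_rho else coexpr_pairs(pred_rho)
  truth <- if (is.data.frame(truth_rho)) truth_rho else coexpr_pairs(truth_rho)
  df <- dplyr::inner_join(pred, truth,
    by = c("gene_a", "gene_b"), suffix = c("_pred", "_truth")
  ) |>
    dplyr::filter(!is.na(.data$rho_pred), !is.na(.data$rho_truth))
  if (nrow(df) == 0L) abort("no common defined pairs between pred and truth")

  labels <- abs(df$rho_truth) >= rho_min
  scores <- abs(df$rho_pred)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  rmse <- sqrt(mean((df$rho_pred - df$rho_truth)^2))

  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # one operating point per distinct score (threshold = that score)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- sc[last]

  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, if (n_neg) fp / n_neg else rep(0, length(fp))),
    tpr = c(0, if (n_pos) tp / n_pos else rep(0, length(tp)))
  )
  pr <- tibble::tibble(
    threshold = thr,
    recall = if (n_pos) tp / n_pos else rep(0, length(tp)),
    precision = tp / (tp + fp)
  )
  trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  auroc <- if (n_pos && n_neg) trapezoid(roc$fpr, roc$tpr) else NA_real_
  auprc <- if (n_pos) {
    trapezoid(c(pr$recall[1], pr$recall), c(pr$precision[1], pr$precision))
  } else NA_real_
  if (n_pos == 0L) warn("no positive pairs: precision-recall undefined")

  structure(
    list(
      roc = roc, pr = pr, auroc = auroc, auprc = auprc, rmse = rmse,
      n_pairs = nrow(df), n_positive = n_pos, rho_min = rho_min,
      pr_unstable = n_pos < 30L
    ),
    class = "coexpr_metrics"
  )
}

#' @export
print.coexpr_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<coexpr_metrics> %d pairs, %d positive (|rho_truth| >= %g)\n",
      "  AUROC %.4f | AUPRC %.4f%s | correlation RMSE %.5f\n"
    ),
    x$n_pairs, x$n_positive, x$rho_min, x$auroc, x$auprc,
    if (isTRUE(x$pr_unstable)) " (unstable: <30 positives)" else "", x$rmse
  ))
  invisible(x)
}

#' @rdname coexpr_metrics
#' @param x A `coexpr_metrics` object.
#' @param ... Unused.
#' @method glance coexpr_metrics
#' @export
glance.coexpr_metrics <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, auprc = x$auprc, rmse = x$rmse,
    n_pairs = x$n_pairs, n_positive = x$n_positive, rho_min = x$rho_min
  )
}

#' @rdname coexpr_metrics
#' @param object A `coexpr_metrics` object.
#' @method autoplot coexpr_metrics
#' @export
autoplot.coexpr_metrics <- function(object, ...) {
  roc <- dplyr::mutate(object$roc, curve = "ROC", x = .data$fpr, y = .data$tpr)
  pr <- dplyr::mutate(object$pr, curve = "Precision-recall",
                      x = .data$recall, y = .data$precision)
  df <- dplyr::bind_rows(
    dplyr::select(roc, "curve", "x", "y"),
    dplyr::select(pr, "curve", "x", "y")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(
      x = "false-positive rate / recall", y = "true-positive rate / precision",
      title = sprintf("Association recovery (|rho_truth| >= %g)", object$rho_min)
    ) +
    ggplot2::theme_minimal()
}

#' Spearman correlations between cross-group exclusive gene pairs
#'
#' Extracts every pair of exclusive genes belonging to *different* groups and
#' attaches their correlation — pairs that share no biological signal, so any
#' systematic co-expression among them is a normalization artifact.
#'
#' @param rho Correlation matrix or pair tibble over a universe containing
#'   the exclusive genes.
#' @param exclusive_genes Tibble with columns `group` and `gene_id` (as in
#'   `snail_sim$exclusive_genes` or [tissue_exclusive_genes()]).
#' @return A tibble `gene_a`, `gene_b`, `group_a`, `group_b`, `rho` with
#'   `group_a != group_b`.
#' @export
cross_group_pairs <- function(rho, exclusive_genes) {
  pairs <- if (is.data.frame(rho)) rho else {
    coexpr_pairs(rho, gene_subset = intersect(rownames(rho), exclusive_genes$gene_id))
  }
  lookup <- setNames(exclusive_genes$group, exclusive_genes$gene_id)
  pairs |>
    dplyr::mutate(
      group_a = unname(lookup[.data$gene_a]),
      group_b = unname(lookup[.data$gene_b])
    ) |>
    dplyr::filter(
      !is.na(.data$group_a), !is.na(.data$group_b),
      .data$group_a != .data$group_b
    )
}

#' Predict gene function from co-expression neighbours
#'
#' Guilt-by-association function prediction: a target gene's neighbours are
#' the genes whose correlation with it reaches `rho_min` (signed by
#' default); a function label is predicted when *more than* `prop_min` of
#' the neighbours carry it. Predictions are scored against the annotation
#' table by the Jaccard index, averaged over target genes that have at least
#' one true label. Targets with no neighbours predict the empty set.
#'
#' @param rho Correlation matrix over a universe containing the targets.
#' @param annotations Tibble with columns `gene_id` and `label`.
#' @param rho_min Correlation threshold defining a co-expression neighbour.
#' @param prop_min Proportion of annotated neighbours required (strict
#'   inequality).
#' @param target_genes Genes to predict for (default: all annotated genes
#'   present in `rho`).
#' @param signed Use signed `rho >= rho_min` (default) or `|rho|`.
#' @return A list with `predictions` (tibble: `gene_id`, `n_neighbours`,
#'   `predicted` and `truth` list-columns, `jaccard`) and `mean_jaccard`.
#' @export
function_prediction <- function(rho, annotations, rho_min = 0.3, prop_min = 0.1,
                                target_genes = NULL, signed = TRUE) {
  ids <- rownames(rho)
  ann <- split(annotations$label, annotations$gene_id)
  if (is.null(target_genes)) target_genes <- intersect(ids, names(ann))
  missing <- setdiff(target_genes, ids)
  if (length(missing)) {
    abort(paste0("target genes not in rho: ", paste(missing, collapse = ", ")))
  }
  res <- purrr::map_dfr(target_genes, function(g) {
    r <- rho[g, ]
    r[g] <- NA_real_
    score <- if (signed) r else abs(r)
    neigh <- ids[!is.na(score) & score >= rho_min]
    pred <- character(0)
    if (length(neigh)) {
      lab <- unlist(ann[intersect(neigh, names(ann))], use.names = FALSE)
      if (length(lab)) {
        prop <- table(lab) / length(neigh)
        pred <- names(prop)[prop > prop_min]
      }
    }
    truth <- unique(ann[[g]] %||% character(0))
    jac <- if (length(truth) == 0L && length(pred) == 0L) {
      NA_real_
    } else {
      length(intersect(pred, truth)) / length(union(pred, truth))
    }
    tibble::tibble(
      gene_id = g, n_neighbours = length(neigh),
      predicted = list(sort(pred)), truth = list(sort(truth)), jaccard = jac
    )
  })
  scored <- res$jaccard[lengths(res$truth) > 0L]
  list(predictions = res, mean_jaccard = mean(scored))
}
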
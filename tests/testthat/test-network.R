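spearman_of <- function(m) {
  ranks <- t(apply(m, 1, rank))
  suppressWarnings(cor(t(ranks)))
}

test_that("sample-specific edges obey the linear decomposition exactly", {
  m <- random_tiefree(8, 10, seed = 501)
  edges <- lioness_edges(m)
  n <- ncol(m)
  e_all <- spearman_of(m)
  ut <- upper.tri(e_all)

  # brute-force oracle, pair by pair
  for (s in c(1, 5, 10)) {
    e_loo <- spearman_of(m[, -s])
    expect_equal(edges[[colnames(m)[s]]], (n * e_all - (n - 1) * e_loo)[ut],
                 tolerance = 1e-12)
  }

  # averaging the sample networks recovers n*e(all) - (n-1)*mean(e(loo))
  loo_mean <- Reduce(`+`, lapply(seq_len(n), function(s) {
    spearman_of(m[, -s])
  })) / n
  w <- as.matrix(edges[, colnames(m)])
  expect_equal(rowMeans(w), (n * e_all - (n - 1) * loo_mean)[ut],
               tolerance = 1e-12)
})

test_that("identical leave-one-out correlations give constant edges", {
  # two perfectly monotone genes: every subset has rho = 1
  m <- rbind(a = 1:6, b = (1:6)^2, c = 100 - (1:6))
  colnames(m) <- paste0("s", 1:6)
  edges <- lioness_edges(m)
  ab <- as.numeric(edges[edges$gene_a == "a" & edges$gene_b == "b",
                         paste0("s", 1:6)])
  expect_equal(ab, rep(1, 6))
})

test_that("group aggregation is the arithmetic mean of sample networks", {
  m <- random_tiefree(6, 8, seed = 502)
  edges <- lioness_edges(m)
  groups <- split_groups(m, 2)
  agg <- aggregate_networks(edges, groups)
  w <- as.matrix(edges[, groups$sample_id[groups$group == "grp1"]])
  expect_equal(agg$weight[agg$group == "grp1"], rowMeans(w))

  # one sample per group: aggregation is the sample network itself
  solo <- tibble::tibble(sample_id = colnames(m), group = colnames(m))
  agg1 <- aggregate_networks(edges, solo)
  first <- agg1[agg1$group == colnames(m)[1], ]
  expect_equal(first$weight, edges[[colnames(m)[1]]])
})

test_that("HITS hub scores match closed forms and eigen decomposition", {
  # unweighted star K_{1,3}: centre sqrt(3) times each leaf
  star <- tibble::tibble(
    gene_a = c("hub", "hub", "hub"),
    gene_b = c("l1", "l2", "l3"),
    weight = 1
  )
  hs <- hub_scores(star)
  centre <- hs$score[hs$gene_id == "hub"]
  leaves <- hs$score[hs$gene_id != "hub"]
  expect_equal(centre, sqrt(3) / (sqrt(3) + 3), tolerance = 1e-6)
  expect_equal(centre / leaves, rep(sqrt(3), 3), tolerance = 1e-6)
  expect_equal(sum(hs$score), 1)

  # complete graph with equal weights: uniform scores
  cg <- tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"), weight = 0.4
  )
  expect_equal(hub_scores(cg)$score, rep(1 / 3, 3))

  # random weighted network: principal eigenvector of A A^T (via eigen),
  # invariance under global rescaling, non-negativity
  withr::with_seed(503, {
    ids <- paste0("g", 1:6)
    pairs <- t(utils::combn(ids, 2))
    net <- tibble::tibble(
      gene_a = pairs[, 1], gene_b = pairs[, 2],
      weight = runif(nrow(pairs), -1, 1)
    )
  })
  hs2 <- hub_scores(net)
  a <- matrix(0, 6, 6, dimnames = list(ids, ids))
  a[cbind(match(net$gene_a, ids), match(net$gene_b, ids))] <- abs(net$weight)
  a <- a + t(a)
  ev <- abs(eigen(a %*% t(a), symmetric = TRUE)$vectors[, 1])
  expect_equal(hs2$score, ev / sum(ev), tolerance = 1e-6)
  expect_true(all(hs2$score >= 0))
  net_scaled <- dplyr::mutate(net, weight = weight * 37)
  expect_equal(hub_scores(net_scaled)$score, hs2$score, tolerance = 1e-8)

  expect_warning(
    hub_scores(tibble::tibble(gene_a = "a", gene_b = "b", weight = 0)),
    "all-zero"
  )
})

test_that("edge t-tests match Welch results and flag shifted edges", {
  withr::with_seed(504, {
    n_pairs <- 60
    base <- matrix(rnorm(n_pairs * 50), n_pairs, 50,
                   dimnames = list(NULL, paste0("x", 1:50)))
    shifted <- base[, 1:50] + 5
    colnames(shifted) <- paste0("y", 1:50)
    pairs <- tibble::tibble(
      gene_a = sprintf("a%02d", 1:n_pairs),
      gene_b = sprintf("b%02d", 1:n_pairs)
    )
  })
  ea <- dplyr::bind_cols(pairs, tibble::as_tibble(base))
  eb <- dplyr::bind_cols(pairs, tibble::as_tibble(shifted))
  res <- edge_ttests(ea, eb)
  expect_true(all(res$significant))

  # identical distributions: t = 0, p = 1
  same <- edge_ttests(ea, dplyr::rename_with(ea, ~ paste0(.x, "_b"),
                                             dplyr::starts_with("x")))
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_value == 1))

  # agreement with stats::t.test for a handful of edges
  for (i in c(1, 17, 42)) {
    tt <- stats::t.test(base[i, ], shifted[i, ])
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("the edge-test FDR holds under the null", {
  withr::with_seed(505, {
    frac <- replicate(20, {
      n_pairs <- 200
      a <- matrix(rnorm(n_pairs * 30), n_pairs, 30,
                  dimnames = list(NULL, paste0("x", 1:30)))
      b <- matrix(rnorm(n_pairs * 30), n_pairs, 30,
                  dimnames = list(NULL, paste0("y", 1:30)))
      pairs <- tibble::tibble(
        gene_a = sprintf("a%03d", 1:n_pairs),
        gene_b = sprintf("b%03d", 1:n_pairs)
      )
      res <- edge_ttests(dplyr::bind_cols(pairs, tibble::as_tibble(a)),
                         dplyr::bind_cols(pairs, tibble::as_tibble(b)))
      mean(res$significant)
    })
  })
  expect_lte(mean(frac), 0.05)
})

test_that("exclusive genes peak as hubs in their own group's network", {
  run <- benchmark_run(benchmark_seeds[1])
  sim <- run$sim
  edges <- lioness_edges(run$ns, sim$exclusive_genes$gene_id)
  hubs <- hub_scores(aggregate_networks(edges, sim$groups))
  j <- dplyr::inner_join(hubs, sim$exclusive_genes, by = "gene_id",
                         suffix = c("_net", "_gene"))
  per_gene <- j |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarize(
      own = .data$score[.data$group_net == .data$group_gene[1]][1],
      best_other = max(.data$score[.data$group_net != .data$group_gene[1]])
    )
  expect_gt(mean(per_gene$own > per_gene$best_other), 0.9)
})
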
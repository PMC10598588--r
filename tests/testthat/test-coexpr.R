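test_that("Spearman matrix handles monotone pairs, sign flips, and constants", {
  x <- c(1, 4, 9, 16, 25, 30)
  m <- rbind(up = x, mono = x^3 + 2, down = 100 - x, flat = rep(3, 6))
  colnames(m) <- paste0("s", 1:6)
  expect_message(rho <- spearman_matrix(m), "constant")
  expect_equal(rho["up", "mono"], 1)
  expect_equal(rho["up", "down"], -1)
  expect_true(all(is.na(rho["flat", ])))
  expect_equal(attr(rho, "n_undefined"), 1L)
  expect_equal(unclass(rho)[1:3, 1:3], t(unclass(rho)[1:3, 1:3]))
  expect_error(spearman_matrix(m[, 1:2]), "samples")
})

test_that("Spearman is invariant under strictly monotone per-gene transforms", {
  m <- random_tiefree(15, 10, seed = 301)
  rho <- spearman_matrix(m)
  m2 <- m
  m2[1, ] <- exp(m2[1, ] / 50)
  m2[2, ] <- m2[2, ]^3
  rho2 <- spearman_matrix(m2)
  expect_equal(unclass(rho), unclass(rho2))
})

test_that("applying a fitted reference depends only on within-sample ranks", {
  # For a fixed fitted model, normalized values are a rank lookup per
  # sample, so any strictly monotone per-sample distortion of the data (the
  # kind of technical variation quantile methods exist to remove) leaves
  # the output — and hence all downstream co-expression — exactly
  # unchanged on tie-free data. (The fit itself does depend on the values:
  # the references are built from the order statistics.)
  m <- random_tiefree(20, 8, seed = 302)
  distorted <- m
  distorted[, 1] <- exp(m[, 1] / 40)
  distorted[, 2] <- m[, 2]^3
  distorted[, 3] <- 10 * m[, 3] + 7
  groups <- split_groups(m, 2)
  fit <- fit_snail(m, groups)
  expect_equal(apply_snail(distorted, fit, groups),
               apply_snail(m, fit, groups))
  fq <- fit_qsmooth(m, groups)
  expect_equal(apply_qsmooth(distorted, fq, groups),
               apply_qsmooth(m, fq, groups))
})

test_that("group-exclusive genes are identified by the median rule", {
  groups <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    group = rep(c("A", "B", "C"), each = 3)
  )
  m <- rbind(
    excl_a = c(12, 12, 13, 0, 0, 0, 0.5, 0.5, 0.4), # A: 12, B: 0, C: 0.5
    leaky = c(12, 12, 13, 5, 5, 6, 0, 0, 0), #  B median 5 breaks rule (ii)
    weak = c(9.9, 9.9, 9.8, 0, 0, 0, 0, 0, 0), # rule (i) fails
    flat = rep(2, 9)
  )
  colnames(m) <- groups$sample_id
  res <- tissue_exclusive_genes(m, groups)
  expect_equal(res$gene_id, "excl_a")
  expect_equal(res$group, "A")
  expect_error(tissue_exclusive_genes(m, groups, hi = 1, lo = 1), "exceed")
})

test_that("the Bonferroni correlation threshold inverts the t approximation", {
  expect_equal(bonferroni_rho_threshold(12, 1), 0.5760, tolerance = 1e-3)

  # threshold grows with the number of tests, shrinks with samples
  t1 <- bonferroni_rho_threshold(20, 100)
  expect_gt(bonferroni_rho_threshold(20, 200), t1)
  expect_lt(bonferroni_rho_threshold(40, 100), t1)
  expect_lt(bonferroni_rho_threshold(12, 1, alpha = 0.999), 0.01)

  # permutation null at n = 12: the threshold sits near the 5% tail
  n <- 12
  thr <- bonferroni_rho_threshold(n, 1)
  withr::with_seed(400, {
    rhos <- replicate(4000, cor(seq_len(n), sample(n), method = "spearman"))
  })
  expect_lt(abs(mean(abs(rhos) >= thr) - 0.05), 0.015)

  expect_error(bonferroni_rho_threshold(3, 1), "4 samples")
})

test_that("co-expression metrics recover perfect and inverted predictions", {
  m <- random_tiefree(12, 30, seed = 303)
  rho <- spearman_matrix(m)
  self <- coexpr_metrics(rho, rho, rho_min = 0.3)
  expect_equal(self$rmse, 0)
  expect_equal(self$auroc, 1)
  expect_equal(max(self$pr$precision), 1)

  neg <- -unclass(rho)
  diag(neg) <- 1
  class(neg) <- class(rho)
  flipped <- coexpr_metrics(neg, rho, rho_min = 0.3)
  expect_equal(flipped$auroc, 1) # |rho| ranking unchanged
  pairs <- coexpr_pairs(rho)
  expect_equal(flipped$rmse, 2 * sqrt(mean(pairs$rho^2)))
})

test_that("random scores give chance-level AUROC on balanced labels", {
  withr::with_seed(404, {
    n <- 2e4
    pred <- tibble::tibble(
      gene_a = sprintf("a%05d", 1:n), gene_b = sprintf("b%05d", 1:n),
      rho = runif(n, -1, 1)
    )
    truth <- pred
    truth$rho <- sample(c(-0.9, 0), n, replace = TRUE) # half positive at 0.3
  })
  met <- coexpr_metrics(pred, truth, rho_min = 0.3)
  expect_equal(met$auroc, 0.5, tolerance = 0.05)
  expect_equal(met$auprc, 0.5, tolerance = 0.05)
})

test_that("function prediction applies the strict neighbour-proportion rule", {
  # target t: 10 neighbours at rho 0.9; 4 of them annotated "X"
  ids <- c("t", paste0("n", 1:10), "far")
  rho <- matrix(-0.5, 12, 12, dimnames = list(ids, ids))
  diag(rho) <- 1
  rho["t", paste0("n", 1:10)] <- 0.9
  rho[paste0("n", 1:10), "t"] <- 0.9
  ann <- tibble::tibble(
    gene_id = c(paste0("n", 1:4), "t", "t"),
    label = c(rep("X", 4), "X", "Y")
  )
  res <- function_prediction(rho, ann, rho_min = 0.5, prop_min = 0.3,
                             target_genes = "t")
  expect_equal(res$predictions$predicted[[1]], "X") # 0.4 > 0.3
  expect_equal(res$predictions$n_neighbours, 10L)
  # truth {X, Y}, predicted {X}: Jaccard 1/2
  expect_equal(res$mean_jaccard, 0.5)

  strict <- function_prediction(rho, ann, rho_min = 0.5, prop_min = 0.4,
                                target_genes = "t")
  expect_equal(strict$predictions$predicted[[1]], character(0)) # 0.4 not > 0.4
  expect_equal(strict$mean_jaccard, 0)

  # no neighbours: empty prediction
  none <- function_prediction(rho, ann, rho_min = 0.95, prop_min = 0.1,
                              target_genes = "t")
  expect_equal(none$predictions$n_neighbours, 0L)
  expect_equal(none$mean_jaccard, 0)
})
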
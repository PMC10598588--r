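# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# genes x samples tibble of zero-inflated negative-binomial counts
random_counts <- function(n_genes, n_samples, seed, zero_prob = 0.4,
                          mu = 20, size = 2) {
  withr::with_seed(seed, {
    m <- matrix(
      rnbinom(n_genes * n_samples, mu = mu, size = size),
      n_genes, n_samples,
      dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:n_samples))
    )
    m[matrix(runif(length(m)) < zero_prob, nrow(m))] <- 0
    m
  })
}

# continuous positive matrix: ties have probability zero
random_tiefree <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    matrix(
      runif(n_genes * n_samples, 0.01, 100),
      n_genes, n_samples,
      dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:n_samples))
    )
  })
}

one_group <- function(m) {
  tibble::tibble(sample_id = colnames(m), group = "all")
}

split_groups <- function(m, k = 2) {
  tibble::tibble(
    sample_id = colnames(m),
    group = paste0("grp", rep_len(seq_len(k), ncol(m)))
  )
}

# the 4-gene / 3-sample worked example: one group, shared zeros,
# qsmooth turns s1's zeros into 4/3 while SNAIL keeps them at 0
worked_example <- function() {
  m <- matrix(
    c(
      0, 0, 0, 9,
      0, 0, 6, 9,
      0, 0, 6, 9
    ),
    nrow = 4,
    dimnames = list(paste0("g", 1:4), paste0("s", 1:3))
  )
  list(counts = m, groups = one_group(m))
}

# Brute-force classical quantile normalization: sort each column (stable),
# replace rank u by the mean of the u-th order statistics, un-sort, then give
# tied raw values the mean of their assigned values. Written independently of
# the package internals.
classic_qn <- function(m) {
  g <- nrow(m)
  ord <- apply(m, 2, function(v) order(v, seq_along(v)))
  sorted <- vapply(seq_len(ncol(m)), function(s) m[ord[, s], s], numeric(g))
  ref <- rowMeans(sorted)
  out <- m
  for (s in seq_len(ncol(m))) {
    assigned <- numeric(g)
    assigned[ord[, s]] <- ref
    for (v in unique(m[, s])) {
      idx <- m[, s] == v
      assigned[idx] <- mean(assigned[idx])
    }
    out[, s] <- assigned
  }
  out
}
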
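# Seeded generator of heterogeneous multi-group count data with known ground
# truth. The design reproduces, at desk scale, the data structure that makes
# classic smooth quantile normalization misbehave: several biological groups,
# group-exclusive genes that are exactly zero elsewhere, and per-sample
# sequencing depths (hence zero fractions) spanning an order of magnitude, so
# the zero tie group covers very different rank ranges in different samples.

#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulate multi-group RNA-Seq counts with known ground truth
#'
#' Generates a genes-by-samples count matrix over several biological groups,
#' together with the pre-distortion ("ground truth") expression, group
#' labels, the identity of group-exclusive genes, and synthetic function
#' annotations. Ground truth is a continuous gamma expression level with
#' gene-specific log-normal means identical in all groups for shared genes;
#' each group also owns a block of exclusive genes with high truth
#' expression inside the group and only a trace baseline
#' (`offgroup_baseline`) outside it, so cross-group exclusive pairs carry no
#' shared biological signal and their ground-truth correlation is
#' structurally near zero. Observed counts are Poisson draws of the truth at
#' a per-sample relative depth (library factors drawn log-uniformly over
#' `libsize_range`, depth = factor / max factor; marginally each count is
#' negative-binomial with dispersion `nb_dispersion`) plus depth-dependent
#' dropout, which makes per-sample zero fractions vary widely — the
#' precondition for tie-rank artifacts: off-group exclusive counts are
#' almost all zero, and the zero tie group spans very different rank ranges
#' across samples.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Total number of samples, split as evenly as possible
#'   across groups.
#' @param n_groups Number of biological groups.
#' @param n_exclusive_per_group Exclusive genes per group
#'   (`n_groups * n_exclusive_per_group < n_genes`).
#' @param libsize_range Length-2 multiplicative span `(lo, hi)` of library
#'   factors, `0 < lo <= hi`.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param zero_inflation Maximum extra dropout probability for the
#'   shallowest sample (scaled by `1 - depth` per sample), on top of
#'   `dropout_base`.
#' @param dropout_base Depth-independent dropout probability applied to every
#'   sample.
#' @param mean_log,sd_log Log-normal parameters of shared-gene mean
#'   expression.
#' @param exclusive_mean Median in-group mean expression of exclusive genes;
#'   per-gene means are log-normal around it (sdlog 1) and floored at 12 so
#'   in-group medians clear the exclusivity threshold, while weakly expressed
#'   exclusive genes still occur (as they do in real tissues).
#' @param n_spikes,spike_mean Number of spike-in transcripts appended to the
#'   matrix (gene IDs `spike001`...) and the median of their fixed abundance
#'   (log-normal across spikes, identical in every sample). Spike-ins pass
#'   through the same Poisson sampling and dropout as every other gene, so
#'   their per-sample totals measure the combined technical loss;
#'   [spike_in_scale()] on the counts rebuilds the validation ("ground
#'   truth") expression the way ERCC controls do.
#' @param n_modules,module_size Number and size of latent co-expression
#'   modules among shared genes: each module's genes share a log-normal
#'   sample-level factor with gene-specific loadings drawn in (0.25, 0.95),
#'   producing genuine associations from weak to strong while leaving every
#'   gene's mean identical across groups.
#' @param offgroup_baseline Trace mean expression of exclusive genes outside
#'   their group (default 0.1): the stray-read level real tissue-exclusive
#'   genes show, small enough that off-group counts are almost all zero yet
#'   keeping ground-truth correlations free of tie structure. Set to 0 for
#'   exact zeros.
#' @param seed Integer seed; regeneration with identical parameters and seed
#'   is bit-identical. The caller's RNG state is left untouched.
#' @return An object of class `snail_sim`: a list with `counts` and `truth`
#'   (tibbles, first column `gene_id`), `groups` (`sample_id`, `group`),
#'   `exclusive_genes` (`group`, `gene_id`), `annotations`
#'   (`gene_id`, `label`), and `params`.
#' @examples
#' sim <- simulate_coexpr_data(n_genes = 100, n_samples = 24, n_groups = 3,
#'                             n_exclusive_per_group = 5, seed = 42)
#' sim
#' @export
simulate_coexpr_data <- function(n_genes = 2000, n_samples = 120, n_groups = 4,
                                 n_exclusive_per_group = 25,
                                 libsize_range = c(1, 20),
                                 nb_dispersion = 0.4, zero_inflation = 0.2,
                                 dropout_base = 0.3,
                                 mean_log = log(50), sd_log = 1.6,
                                 exclusive_mean = 30, offgroup_baseline = 0.1,
                                 n_modules = 10, module_size = 40,
                                 n_spikes = 96, spike_mean = 60,
                                 seed = 1) {
  if (length(libsize_range) != 2L || libsize_range[1] <= 0 ||
      libsize_range[2] < libsize_range[1]) {
    abort("libsize_range must be (lo, hi) with 0 < lo <= hi")
  }
  if (n_groups * n_exclusive_per_group >= n_genes) {
    abort("n_groups * n_exclusive_per_group must be smaller than n_genes")
  }
  if (n_samples < 2L * n_groups) {
    abort("need at least 2 samples per group")
  }
  params <- list(
    n_genes = n_genes, n_samples = n_samples, n_groups = n_groups,
    n_exclusive_per_group = n_exclusive_per_group,
    libsize_range = libsize_range, nb_dispersion = nb_dispersion,
    zero_inflation = zero_inflation, dropout_base = dropout_base,
    mean_log = mean_log, sd_log = sd_log,
    exclusive_mean = exclusive_mean, offgroup_baseline = offgroup_baseline,
    n_modules = n_modules, module_size = module_size,
    n_spikes = n_spikes, spike_mean = spike_mean, seed = seed
  )

  gene_ids <- c(
    sprintf("g%04d", seq_len(n_genes)),
    if (n_spikes > 0) sprintf("spike%03d", seq_len(n_spikes))
  )
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  group_labels <- sprintf("tissue_%d", seq_len(n_groups))
  grp <- group_labels[(seq_len(n_samples) - 1L) %% n_groups + 1L]

  n_excl <- n_groups * n_exclusive_per_group
  excl_idx <- split(seq_len(n_excl), rep(group_labels, each = n_exclusive_per_group))
  size <- 1 / nb_dispersion

  with_local_seed(seed, {
    # Ground truth is a continuous gamma expression level; observed counts
    # are Poisson draws at the sample's relative depth, so marginally each
    # count is negative-binomial with the requested dispersion.
    rgamma_mu <- function(n, mu) {
      stats::rgamma(n, shape = size, rate = size / mu)
    }
    truth <- matrix(0, n_genes + n_spikes, n_samples,
                    dimnames = list(gene_ids, sample_ids))
    # exclusive genes first: high in their group, trace baseline elsewhere
    for (gl in group_labels) {
      rows <- excl_idx[[gl]]
      on <- grp == gl
      mu <- pmax(12, rlnorm(length(rows), log(exclusive_mean), 1.0))
      truth[rows, on] <- rgamma_mu(length(rows) * sum(on), rep(mu, times = sum(on)))
      if (offgroup_baseline > 0) {
        truth[rows, !on] <- rgamma_mu(length(rows) * sum(!on), offgroup_baseline)
      }
    }
    # shared genes: one mean per gene, identical across groups; the first
    # genes belong to co-expression modules driven by sample-level latent
    # factors (group-independent), giving genuine associations across a
    # continuum of strengths
    shared <- (n_excl + 1L):n_genes
    mu_shared <- rlnorm(length(shared), mean_log, sd_log)
    mult <- matrix(1, length(shared), n_samples)
    n_mod_genes <- n_modules * module_size
    if (n_mod_genes > 0) {
      if (n_mod_genes > length(shared)) {
        abort("module genes exceed the number of shared genes")
      }
      # module genes are well expressed (co-regulated pathways are detectable
      # precisely because their members are not drowned in zeros)
      mu_shared[seq_len(n_mod_genes)] <- rlnorm(n_mod_genes, log(80), 0.8)
      loading <- runif(n_mod_genes, 0.25, 0.95)
      for (mod in seq_len(n_modules)) {
        z <- stats::rnorm(n_samples)
        rows <- ((mod - 1L) * module_size + 1L):(mod * module_size)
        l <- loading[rows]
        mult[rows, ] <- exp(outer(l, z) - l^2 / 2)
      }
    }
    truth[shared, ] <- rgamma_mu(length(shared) * n_samples,
      rep(mu_shared, times = n_samples) * as.vector(mult)
    )
    if (n_spikes > 0) {
      # spike-in transcripts: fixed known abundance, identical in all samples
      spike_rows <- (n_genes + 1L):(n_genes + n_spikes)
      truth[spike_rows, ] <- rlnorm(n_spikes, log(spike_mean), 1)
    }

    lib <- exp(runif(n_samples, log(libsize_range[1]), log(libsize_range[2])))
    depth <- lib / libsize_range[2]
    counts <- truth
    n_rows <- nrow(truth)
    for (s in seq_len(n_samples)) {
      counts[, s] <- stats::rpois(n_rows, lambda = truth[, s] * depth[s])
      drop <- runif(n_rows) < dropout_base + zero_inflation * (1 - depth[s])
      counts[drop, s] <- 0
    }

    out <- list(
      counts = as_count_tibble(counts),
      truth = as_count_tibble(truth),
      groups = tibble::tibble(sample_id = sample_ids, group = grp),
      exclusive_genes = tibble::tibble(
        group = rep(group_labels, each = n_exclusive_per_group),
        gene_id = gene_ids[seq_len(n_excl)]
      ),
      annotations = tibble::tibble(
        gene_id = gene_ids[seq_len(n_excl)],
        label = paste0("function_", rep(group_labels, each = n_exclusive_per_group))
      ),
      spike_genes = if (n_spikes > 0) gene_ids[(n_genes + 1L):(n_genes + n_spikes)] else character(0),
      library_factors = tibble::tibble(sample_id = sample_ids, factor = lib),
      params = params
    )
    class(out) <- "snail_sim"
    out
  })
}

#' @export
print.snail_sim <- function(x, ...) {
  p <- x$params
  zf <- colMeans(as_count_matrix(x$counts, require_samples = 1L) == 0)
  cat(sprintf(
    paste0(
      "<snail_sim> %d genes x %d samples, %d groups, %d exclusive genes/group\n",
      "  library span %gx-%gx, per-sample zero fraction %.2f-%.2f, seed %d\n"
    ),
    p$n_genes, p$n_samples, p$n_groups, p$n_exclusive_per_group,
    p$libsize_range[1], p$libsize_range[2], min(zf), max(zf), p$seed
  ))
  invisible(x)
}

#' Ground-truth gene associations of a simulated dataset
#'
#' Gene pairs whose Spearman correlation on the ground-truth expression has
#' absolute value at least `rho_min` — the positives against which
#' normalized co-expression is evaluated.
#'
#' @param sim A `snail_sim` object, or a truth counts data frame/matrix.
#' @param rho_min Threshold on `|rho|`, in `[0, 1]`.
#' @param gene_subset Optional character vector restricting the gene
#'   universe.
#' @return A tibble with columns `gene_a`, `gene_b` (`gene_a < gene_b`) and
#'   `rho`.
#' @export
truth_associations <- function(sim, rho_min = 0.3, gene_subset = NULL) {
  if (rho_min < 0 || rho_min > 1) abort("rho_min must be in [0, 1]")
  truth <- if (inherits(sim, "snail_sim")) sim$truth else sim
  rho <- spearman_matrix(truth, gene_subset)
  coexpr_pairs(rho) |>
    dplyr::filter(!is.na(.data$rho), abs(.data$rho) >= rho_min)
}
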
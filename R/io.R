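#' Read a genes-by-samples count table
#'
#' Reads a delimited text file with gene identifiers in the first column and
#' one column per sample. Values must be nonnegative numbers with no missing
#' entries; duplicated gene or sample identifiers are rejected, as is a table
#' too small to normalize (fewer than 2 genes or 2 samples).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A tibble whose first column is `gene_id` (character) followed by
#'   one numeric column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t5", "g2\t3\t1"), tf)
#' read_counts(tf)
#' @export
read_counts <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  # parsing problems surface as errors below, not as readr warnings
  df <- suppressWarnings(reader(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf(
      "malformed numeric cell at row %d, column %d of %s",
      probs$row[1L], probs$col[1L], path
    ))
  }
  names(df)[1L] <- "gene_id"
  as_count_matrix(df) # validation only
  tibble::as_tibble(df)
}

#' Write a count table to delimited text
#'
#' Inverse of [read_counts()]: numeric values are written with enough digits
#' that a round trip reproduces the input to the requested precision (exactly,
#' for integer counts).
#'
#' @param counts Counts data frame or matrix (see [read_counts()]).
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @param digits Decimal places retained for non-integer values.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "csv"), digits = 6) {
  format <- match.arg(format)
  m <- as_count_matrix(counts, require_samples = 1L)
  df <- as_count_tibble(round(m, digits))
  if (format == "tsv") {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' Two tab-separated columns, `sample_id` then `group`; no header by default.
#'
#' @param path Path to the file.
#' @param header Does the file carry a header line?
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_groups <- function(path, header = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path,
    col_names = if (header) TRUE else c("sample_id", "group"),
    col_types = "cc", progress = FALSE
  )
  names(df)[1:2] <- c("sample_id", "group")
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id in groups file")
  df
}

#' Read a gene-to-function annotation table
#'
#' Two tab-separated columns, `gene_id` then `label`; genes with several
#' functions repeat the gene_id on additional lines.
#'
#' @param path Path to the file.
#' @param header Does the file carry a header line?
#' @return A tibble with columns `gene_id` and `label` (one row per pair).
#' @export
read_annotations <- function(path, header = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path,
    col_names = if (header) TRUE else c("gene_id", "label"),
    col_types = "cc", progress = FALSE
  )
  names(df)[1:2] <- c("gene_id", "label")
  dplyr::distinct(df)
}

#' Scale counts by spike-in totals
#'
#' Rescales each sample by a size factor derived from exogenous spike-in
#' transcripts (e.g. ERCC controls) added at known amounts, yielding a
#' ground-truth-scaled expression table. The default factor for sample
#' \eqn{s} is \eqn{f_s = T_s / \bar{T}} where \eqn{T_s} is the spike-in
#' count total in \eqn{s} and \eqn{\bar{T}} their mean over samples; each
#' column is divided by its factor. `method = "median_ratio"` instead uses
#' the median across spike-ins of the ratio to the spike-in's geometric mean
#' (a DESeq-style factor restricted to spike-ins), renormalized to mean 1.
#'
#' @param counts Counts data frame or matrix.
#' @param spike_genes Character vector of spike-in gene IDs (must all be
#'   present in `counts`).
#' @param keep_spikes Keep spike-in rows in the output (default) or drop them.
#' @param method `"total"` (default) or `"median_ratio"`.
#' @return A tibble in the same shape as `counts`, scaled per sample.
#' @export
spike_in_scale <- function(counts, spike_genes, keep_spikes = TRUE,
                           method = c("total", "median_ratio")) {
  method <- match.arg(method)
  m <- as_count_matrix(counts, require_samples = 1L)
  missing <- setdiff(spike_genes, rownames(m))
  if (length(missing)) {
    abort(paste0("spike-in genes absent from counts: ", paste(missing, collapse = ", ")))
  }
  spikes <- m[spike_genes, , drop = FALSE]
  totals <- colSums(spikes)
  if (any(totals <= 0)) {
    abort(paste0(
      "sample(s) with zero spike-in total: ",
      paste(colnames(m)[totals <= 0], collapse = ", ")
    ))
  }
  if (method == "total") {
    f <- totals / mean(totals)
  } else {
    gm <- exp(rowMeans(log(pmax(spikes, 0.5)))) # pseudocount guards zero spikes
    f <- apply(spikes / gm, 2, median)
    f <- f / mean(f)
  }
  out <- sweep(m, 2, f, `/`)
  if (!keep_spikes) out <- out[setdiff(rownames(out), spike_genes), , drop = FALSE]
  as_count_tibble(out)
}
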
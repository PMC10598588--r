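# Internal representation: user-facing functions take a counts data frame
# (first column `gene_id`, one numeric column per sample) and convert to a
# genes x samples numeric matrix with dimnames for computation.

#' Convert a counts data frame to a genes-by-samples matrix
#'
#' @param counts A data frame whose first column is `gene_id` and whose
#'   remaining columns are numeric per-sample values, or an already-formed
#'   numeric matrix with gene row names and sample column names.
#' @param require_samples Minimum number of sample columns required.
#' @return A numeric matrix with unique row (gene) and column (sample) names.
#' @keywords internal
as_count_matrix <- function(counts, require_samples = 2L) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("count matrix must carry gene row names and sample column names")
    }
  } else if (is.data.frame(counts)) {
    if (ncol(counts) < 2L) {
      abort("counts must have a gene_id column plus at least one sample column")
    }
    gene_ids <- as.character(counts[[1L]])
    body <- counts[, -1L, drop = FALSE]
    bad <- !vapply(body, is.numeric, logical(1))
    if (any(bad)) {
      abort(paste0(
        "non-numeric sample column(s): ",
        paste(names(body)[bad], collapse = ", ")
      ))
    }
    m <- as.matrix(body)
    rownames(m) <- gene_ids
  } else {
    abort("counts must be a data frame or a named numeric matrix")
  }
  validate_count_matrix(m, require_samples = require_samples)
  m
}

#' @keywords internal
validate_count_matrix <- function(m, require_samples = 2L) {
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "negative value at gene '%s', sample '%s'",
      rownames(m)[idx[1L]], colnames(m)[idx[2L]]
    ))
  }
  if (anyDuplicated(rownames(m))) {
    abort(paste0(
      "duplicated gene IDs: ",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(m))) abort("duplicated sample IDs")
  if (nrow(m) < 2L) abort("need at least 2 genes (rows); is the matrix transposed?")
  if (ncol(m) < require_samples) {
    abort(sprintf("need at least %d samples (columns)", require_samples))
  }
  invisible(m)
}

#' Turn a genes-by-samples matrix back into a tibble
#' @keywords internal
as_count_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "gene_id")
}

# Resolve a group assignment against the samples of a matrix. Accepts a
# two-column data frame (sample_id, group) or a named character vector.
#' @keywords internal
resolve_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L) abort("groups must have columns sample_id and group")
    map <- setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  } else if (is.character(groups) && !is.null(names(groups))) {
    map <- groups
  } else {
    abort("groups must be a two-column data frame or a named character vector")
  }
  if (anyDuplicated(names(map))) abort("a sample appears more than once in groups")
  missing <- setdiff(sample_ids, names(map))
  if (length(missing)) {
    abort(paste0("samples without a group label: ", paste(missing, collapse = ", ")))
  }
  factor(unname(map[sample_ids]))
}
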
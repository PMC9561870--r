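#' Sparse UMI count matrix with per-unit metadata
#'
#' `count_matrix()` is the container every stage of the pipeline consumes:
#' a sparse genes x units matrix of non-negative integer UMI counts plus a
#' per-unit metadata table. "Units" are cells for scRNA-seq, capture spots
#' for spatial data. Counts are stored as a `Matrix::dgCMatrix`; gene names
#' are row names, unit barcodes are column names.
#'
#' @param counts matrix-like object of non-negative integer counts,
#'   genes in rows and units in columns. Row and column names are required
#'   and must be unique.
#' @param unit_meta optional `data.frame` with one row per unit (genotype,
#'   tissue, batch, spatial coordinates, ...). Defaults to an empty frame.
#'
#' @return An object of class `"CountMatrix"`: a list with elements
#'   `counts` (dgCMatrix) and `unit_meta` (data.frame keyed by unit id).
#' @export
#' @examples
#' m <- count_matrix(matrix(c(0, 2, 1, 5), 2, 2,
#'   dimnames = list(c("Col1a1", "Sp7"), c("c1", "c2"))))
#' dim(m)
count_matrix <- function(counts, unit_meta = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if ((nrow(counts) && is.null(rownames(counts))) ||
    (ncol(counts) && is.null(colnames(counts)))) {
    stop("counts must carry gene (row) and unit (column) names", call. = FALSE)
  }
  # zero-extent dimensions may legitimately lack names (e.g. after QC
  # removed every unit); normalize them to empty character vectors
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene names in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate unit ids in count matrix", call. = FALSE)
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(unit_meta)) {
    unit_meta <- data.frame(row.names = colnames(counts))
  }
  unit_meta <- as.data.frame(unit_meta)
  if (nrow(unit_meta) != ncol(counts)) {
    stop(sprintf(
      "unit_meta has %d rows but counts has %d units",
      nrow(unit_meta), ncol(counts)
    ), call. = FALSE)
  }
  rownames(unit_meta) <- colnames(counts)
  structure(list(counts = counts, unit_meta = unit_meta),
    class = "CountMatrix"
  )
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d genes x %d units (%d non-zero entries)\n",
    nrow(x$counts), ncol(x$counts), length(x$counts@x)
  ))
  if (ncol(x$unit_meta)) {
    cat("unit_meta:", paste(colnames(x$unit_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gene names, unit ids and per-unit totals
#'
#' Small accessors used throughout the pipeline. `unit_totals()` is the
#' per-unit total UMI count, the denominator of the %UMI normalization.
#'
#' @param m a `CountMatrix`.
#' @return Character vector of names / ids, or named numeric totals.
#' @export
gene_names <- function(m) rownames(assert_count_matrix(m)$counts)

#' @rdname gene_names
#' @export
unit_ids <- function(m) colnames(assert_count_matrix(m)$counts)

#' @rdname gene_names
#' @export
unit_totals <- function(m) Matrix::colSums(assert_count_matrix(m)$counts)

#' Subset a CountMatrix by unit ids and/or gene names
#'
#' @param m a `CountMatrix`.
#' @param units character vector of unit ids to keep (default all).
#' @param genes character vector of gene names to keep (default all).
#' @return A `CountMatrix` restricted to the requested units/genes, in the
#'   requested order.
#' @export
subset_units <- function(m, units = NULL, genes = NULL) {
  m <- assert_count_matrix(m)
  if (is.null(units)) units <- unit_ids(m)
  if (is.null(genes)) genes <- gene_names(m)
  miss <- setdiff(units, unit_ids(m))
  if (length(miss)) {
    stop("unknown unit ids: ", paste(utils::head(miss, 5), collapse = ", "),
      call. = FALSE
    )
  }
  miss <- setdiff(genes, gene_names(m))
  if (length(miss)) {
    stop("unknown genes: ", paste(utils::head(miss, 5), collapse = ", "),
      call. = FALSE
    )
  }
  count_matrix(
    m$counts[genes, units, drop = FALSE],
    m$unit_meta[units, , drop = FALSE]
  )
}

assert_count_matrix <- function(m) {
  if (!inherits(m, "CountMatrix")) {
    stop("expected a CountMatrix (see count_matrix())", call. = FALSE)
  }
  m
}

require_genes <- function(m, genes, context = "gene") {
  miss <- setdiff(genes, gene_names(m))
  if (length(miss)) {
    stop(sprintf(
      "%s(s) not in gene universe: %s", context,
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
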
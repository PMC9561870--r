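#' Relative-count normalization to percent of total UMI
#'
#' Converts raw UMI counts to the pipeline's sole expression unit, %UMI:
#' a gene's UMI count divided by the unit's total UMI count, times 100.
#' No logarithm, no scale factors, no variance stabilization — downstream
#' statistics are designed for the raw relative counts.
#'
#' @param m a `CountMatrix`; every unit must have total UMI > 0 (guaranteed
#'   after QC filtering).
#' @param include_mito logical; keep mitochondrial genes in the per-unit
#'   denominator (default `TRUE`). When `FALSE` the totals exclude genes
#'   matching `mito_prefix` but mitochondrial rows are still reported.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return A `PercentUMIMatrix`: list with `values` (sparse genes x units,
#'   percent scale) and `totals` (per-unit denominator used).
#' @export
#' @examples
#' m <- count_matrix(matrix(c(350, 9650), 2, 1,
#'   dimnames = list(c("Col1a1", "other"), "c1")))
#' to_percent_umi(m)$values["Col1a1", ] # 3.5
to_percent_umi <- function(m, include_mito = TRUE, mito_prefix = "mt-") {
  m <- assert_count_matrix(m)
  totals <- if (include_mito) {
    Matrix::colSums(m$counts)
  } else {
    keep <- !startsWith(gene_names(m), mito_prefix)
    Matrix::colSums(m$counts[keep, , drop = FALSE])
  }
  zero <- totals == 0
  if (any(zero)) {
    stop(
      "unit(s) with zero total UMI: ",
      paste(utils::head(unit_ids(m)[zero], 5), collapse = ", "),
      call. = FALSE
    )
  }
  values <- m$counts %*% Matrix::Diagonal(x = 100 / totals)
  dimnames(values) <- dimnames(m$counts)
  structure(
    list(values = values, totals = totals, unit_meta = m$unit_meta),
    class = "PercentUMIMatrix"
  )
}

#' @export
print.PercentUMIMatrix <- function(x, ...) {
  cat(sprintf(
    "PercentUMIMatrix: %d genes x %d units (percent scale)\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

assert_percent_umi <- function(p) {
  if (!inherits(p, "PercentUMIMatrix")) {
    stop("expected a PercentUMIMatrix (see to_percent_umi())", call. = FALSE)
  }
  p
}

#' Per-unit %UMI values of one gene
#'
#' @param p a `PercentUMIMatrix`.
#' @param gene gene name.
#' @param units optional unit ids (default all).
#' @return Named numeric vector of %UMI values.
#' @export
gene_percent_umi <- function(p, gene, units = NULL) {
  p <- assert_percent_umi(p)
  if (!gene %in% rownames(p$values)) {
    stop("gene not in gene universe: ", gene, call. = FALSE)
  }
  v <- p$values[gene, ]
  if (!is.null(units)) {
    miss <- setdiff(units, names(v))
    if (length(miss)) {
      stop("unknown unit ids: ", paste(utils::head(miss, 5), collapse = ", "),
        call. = FALSE
      )
    }
    v <- v[units]
  }
  v
}

#' UMI-weighted group mean expression (pooled fraction)
#'
#' The group average used everywhere in the pipeline: the sum of a gene's
#' UMI counts across the group's units divided by the sum of all UMI counts
#' in those units, times 100. Equivalent to weighting each unit by its
#' total UMI count; deliberately different from the unweighted mean of
#' per-unit %UMI values.
#'
#' @param m a `CountMatrix`.
#' @param units character vector of unit ids forming the group (non-empty).
#' @param gene gene name (must exist).
#' @return A one-row `data.frame` with `gene`, `weighted_mean` (%UMI) and
#'   `n_units`.
#' @export
#' @examples
#' m <- count_matrix(matrix(c(10, 990, 0, 1000), 2, 2,
#'   dimnames = list(c("g", "rest"), c("c1", "c2"))))
#' weighted_group_mean(m, c("c1", "c2"), "g")$weighted_mean # 0.5
weighted_group_mean <- function(m, units, gene) {
  m <- assert_count_matrix(m)
  if (!length(units)) stop("empty unit group", call. = FALSE)
  require_genes(m, gene)
  miss <- setdiff(units, unit_ids(m))
  if (length(miss)) {
    stop("unknown unit ids: ", paste(utils::head(miss, 5), collapse = ", "),
      call. = FALSE
    )
  }
  sub <- m$counts[, units, drop = FALSE]
  data.frame(
    gene = gene,
    weighted_mean = 100 * sum(sub[gene, ]) / sum(sub),
    n_units = length(units),
    stringsAsFactors = FALSE
  )
}

# Vectorized pooled-fraction means for many genes at once (internal).
pooled_fraction <- function(m, units, genes) {
  sub <- m$counts[, units, drop = FALSE]
  100 * Matrix::rowSums(sub[genes, , drop = FALSE]) / sum(sub)
}
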
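#' Write a CountMatrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (1-based MatrixMarket coordinate format),
#' `genes.tsv`, `barcodes.tsv` and, when unit metadata is present,
#' `meta.tsv` (tab-separated, one row per barcode, barcodes in the first
#' column). The layout round-trips losslessly through [read_matrix()].
#'
#' @param m a `CountMatrix`.
#' @param path directory to write into; created if absent.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- assert_count_matrix(m)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  writeLines(gene_names(m), file.path(path, "genes.tsv"))
  writeLines(unit_ids(m), file.path(path, "barcodes.tsv"))
  if (ncol(m$unit_meta)) {
    meta <- cbind(barcode = unit_ids(m), m$unit_meta)
    utils::write.table(meta, file.path(path, "meta.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a 10x-style triplet directory into a CountMatrix
#'
#' Expects `matrix.mtx` plus gene and barcode name files (`genes.tsv` or
#' `features.tsv`; `barcodes.tsv`). Genes are rows. Duplicate coordinate
#' entries in the MTX file are summed, per MatrixMarket convention. A
#' `meta.tsv` written by [write_matrix()] is restored as unit metadata.
#'
#' @param path directory containing the triplet files.
#' @return A `CountMatrix`.
#' @export
read_matrix <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", path, call. = FALSE)
  gene_file <- file.path(path, "genes.tsv")
  if (!file.exists(gene_file)) gene_file <- file.path(path, "features.tsv")
  bc_file <- file.path(path, "barcodes.tsv")
  if (!file.exists(gene_file) || !file.exists(bc_file)) {
    stop("gene/barcode name files missing under ", path, call. = FALSE)
  }
  genes <- readLines(gene_file)
  # features.tsv may carry id/symbol/type columns; take the first field
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[`, "", 1L)
  barcodes <- readLines(bc_file)
  if (!length(barcodes)) stop("barcode file is empty: ", bc_file, call. = FALSE)
  if (!length(genes)) stop("gene file is empty: ", gene_file, call. = FALSE)
  # triplet form; coercion to CsparseMatrix sums duplicate coordinates
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes)) {
    stop(sprintf(
      "matrix.mtx is %d x %d but %d genes / %d barcodes listed",
      nrow(counts), ncol(counts), length(genes), length(barcodes)
    ), call. = FALSE)
  }
  dimnames(counts) <- list(genes, barcodes)
  meta_file <- file.path(path, "meta.tsv")
  meta <- NULL
  if (file.exists(meta_file)) {
    meta <- utils::read.table(meta_file,
      sep = "\t", header = TRUE,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    rownames(meta) <- meta$barcode
    meta <- meta[barcodes, setdiff(colnames(meta), "barcode"), drop = FALSE]
  }
  count_matrix(counts, meta)
}

#' Merge count matrices without transformation
#'
#' Concatenates datasets unit-wise with no batch correction and no
#' rescaling; counts pass through unchanged. Genes are aligned by name.
#' When the gene universes differ, the intersection is used with a
#' warning. Unit ids colliding with an earlier dataset are suffixed
#' `-<dataset index>` so merging is always deterministic.
#'
#' @param datasets a list of `CountMatrix` objects (length >= 1).
#' @return A single merged `CountMatrix`; unit metadata columns are the
#'   union across datasets, missing values filled with `NA`.
#' @export
merge_matrices <- function(datasets) {
  if (!length(datasets)) stop("no datasets to merge", call. = FALSE)
  datasets <- lapply(datasets, assert_count_matrix)
  if (length(datasets) == 1L) return(datasets[[1L]])

  universes <- lapply(datasets, gene_names)
  genes <- Reduce(intersect, universes)
  if (!length(genes)) stop("gene universes share no genes", call. = FALSE)
  if (any(vapply(universes, function(u) length(u) != length(genes), NA))) {
    warning(sprintf(
      "gene universes differ; merging on %d shared genes", length(genes)
    ), call. = FALSE)
  }
  genes <- universes[[1L]][universes[[1L]] %in% genes]

  seen <- character()
  meta_cols <- unique(unlist(lapply(datasets, function(d) colnames(d$unit_meta))))
  blocks <- vector("list", length(datasets))
  metas <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    ids <- unit_ids(d)
    clash <- ids %in% seen
    ids[clash] <- paste0(ids[clash], "-", i)
    seen <- c(seen, ids)
    block <- d$counts[genes, , drop = FALSE]
    colnames(block) <- ids
    blocks[[i]] <- block
    meta <- d$unit_meta
    for (col in setdiff(meta_cols, colnames(meta))) meta[[col]] <- NA
    meta <- meta[, meta_cols, drop = FALSE]
    rownames(meta) <- ids
    metas[[i]] <- meta
  }
  merged_meta <- if (length(meta_cols)) {
    do.call(rbind, metas)
  } else {
    data.frame(row.names = seen)
  }
  count_matrix(do.call(cbind, blocks), merged_meta)
}
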
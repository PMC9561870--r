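#' Quality-control configuration
#'
#' Osteoblasts carry far more RNA than most cells, so the filters are set
#' permissive on the high side: a floor of 500 detected features per cell,
#' no feature ceiling, and a strict "less than 10% mitochondrial" rule.
#'
#' @param min_features minimum number of genes with count > 0 per unit.
#' @param max_features optional ceiling on detected genes (`NULL` = none).
#' @param max_mito_fraction mitochondrial UMI fraction bound; units are
#'   kept only when their fraction is strictly below it.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @param death_markers genes screened at dataset level, see
#'   [screen_dataset_death_markers()].
#' @param death_screen_alpha significance level of the dataset screen
#'   (Bonferroni-corrected over the markers).
#' @return A `QCConfig` list.
#' @export
qc_config <- function(min_features = 500, max_features = NULL,
                      max_mito_fraction = 0.10, mito_prefix = "mt-",
                      death_markers = c("Apaf1", "Trp53inp1"),
                      death_screen_alpha = 0.05) {
  stopifnot(
    min_features >= 0,
    max_mito_fraction > 0, max_mito_fraction <= 1,
    death_screen_alpha > 0, death_screen_alpha < 1
  )
  structure(
    list(
      min_features = min_features, max_features = max_features,
      max_mito_fraction = max_mito_fraction, mito_prefix = mito_prefix,
      death_markers = death_markers, death_screen_alpha = death_screen_alpha
    ),
    class = "QCConfig"
  )
}

#' Filter cells (or spots) on detected features and mitochondrial load
#'
#' Keeps units with at least `min_features` genes detected (count > 0),
#' at most `max_features` when set, and a mitochondrial UMI fraction
#' strictly below `max_mito_fraction` (a cell at exactly 10.0% is
#' removed). Fractions are computed on raw counts before any gating.
#' Filtering is idempotent.
#'
#' @param m a `CountMatrix`.
#' @param qc a [qc_config()].
#' @return The filtered `CountMatrix` with attribute `"qc_report"`, a
#'   one-row data.frame of input/output unit counts and removals per
#'   criterion. Removing every unit triggers a warning, not an error.
#' @export
filter_cells <- function(m, qc = qc_config()) {
  m <- assert_count_matrix(m)
  n_features <- Matrix::colSums(m$counts > 0)
  totals <- Matrix::colSums(m$counts)
  is_mito <- startsWith(gene_names(m), qc$mito_prefix)
  mito_frac <- if (any(is_mito)) {
    Matrix::colSums(m$counts[is_mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(m$counts))
  }
  pass_min <- n_features >= qc$min_features
  pass_max <- if (is.null(qc$max_features)) {
    rep(TRUE, length(n_features))
  } else {
    n_features <= qc$max_features
  }
  pass_mito <- mito_frac < qc$max_mito_fraction
  keep <- pass_min & pass_max & pass_mito
  report <- data.frame(
    n_in = length(keep), n_out = sum(keep),
    removed_min_features = sum(!pass_min),
    removed_max_features = sum(!pass_max),
    removed_mito = sum(!pass_mito)
  )
  if (!any(keep)) {
    warning("QC removed every unit; returning an empty matrix", call. = FALSE)
  }
  out <- count_matrix(
    m$counts[, keep, drop = FALSE],
    m$unit_meta[keep, , drop = FALSE]
  )
  attr(out, "qc_report") <- report
  out
}

#' Dataset-level cell-death marker screen
#'
#' Compares each death marker's expression in a candidate dataset against
#' a reference dataset from the same pipeline stage, using the pipeline's
#' UMI-weighted means and per-cell rank test. The dataset is flagged for
#' discard when any marker is significantly *elevated* (one direction of
#' a two-sided test) at `death_screen_alpha` after Bonferroni correction
#' over the markers tested. Markers absent from either gene universe are
#' reported as untested, never as failures.
#'
#' @param m candidate `CountMatrix`.
#' @param reference reference `CountMatrix`.
#' @param qc a [qc_config()] supplying `death_markers` and
#'   `death_screen_alpha`.
#' @return A list with `discard` (logical) and `markers`, a data.frame of
#'   per-marker weighted means, raw and adjusted p-values, and status
#'   (`"tested"` / `"untested"`).
#' @export
screen_dataset_death_markers <- function(m, reference, qc = qc_config()) {
  m <- assert_count_matrix(m)
  reference <- assert_count_matrix(reference)
  markers <- qc$death_markers
  testable <- markers[markers %in% gene_names(m) &
    markers %in% gene_names(reference)]
  p_m <- to_percent_umi(m)
  p_r <- to_percent_umi(reference)
  rows <- lapply(markers, function(g) {
    if (!g %in% testable) {
      return(data.frame(
        gene = g, mean_test = NA_real_, mean_reference = NA_real_,
        p_raw = NA_real_, p_adj = NA_real_, elevated = NA,
        status = "untested", stringsAsFactors = FALSE
      ))
    }
    mu_t <- weighted_group_mean(m, unit_ids(m), g)$weighted_mean
    mu_r <- weighted_group_mean(reference, unit_ids(reference), g)$weighted_mean
    p <- rank_test(gene_percent_umi(p_r, g), gene_percent_umi(p_m, g))
    p_adj <- min(1, p * length(testable))
    data.frame(
      gene = g, mean_test = mu_t, mean_reference = mu_r,
      p_raw = p, p_adj = p_adj,
      elevated = mu_t > mu_r & p_adj < qc$death_screen_alpha,
      status = "tested", stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  list(discard = isTRUE(any(tab$elevated, na.rm = TRUE)), markers = tab)
}
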